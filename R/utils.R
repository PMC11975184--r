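# internal constants and helpers shared across modules

# the nine surrogate-model inputs, in canonical column order
CHO_INPUT_FEATURES <- c(
  "do_setpoint", "ph_setpoint", "gln_start", "glc_start", "ph_shift_day",
  "vcd0", "feed_start_day", "glc_feed_target", "process_time"
)

# the four key performance indicators (time-resolved running statistics)
CHO_KPI_NAMES <- c("vcd_max_to_t", "titer_at_t", "diameter_max_to_t", "qp_mean_to_t")

# sentinel for "no feed" / "no pH shift" in numeric tables
CHO_NONE <- -1L

#' Canonical input and output column names
#'
#' The surrogate models map nine process inputs (eight run-level setpoints
#' plus process time) to four key performance indicators.  These helpers
#' return the canonical column names in the order every model in the package
#' expects.
#'
#' @return Character vector of column names.
#' @export
input_features <- function() CHO_INPUT_FEATURES

#' @rdname input_features
#' @export
kpi_names <- function() CHO_KPI_NAMES

# run `expr` with a private RNG state, seeded with `seed`; the caller's
# .Random.seed is restored afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# derive `n` child seeds from one parent seed, all < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_choopt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
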