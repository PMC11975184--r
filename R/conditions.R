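#' Define one cultivation condition
#'
#' A process condition holds the eight run-level setpoints that define a
#' fed-batch CHO cultivation: pH and dissolved-oxygen setpoints, inoculation
#' density, starting glucose and glutamine, the glucose feed target, the
#' feeding start day and an optional pH shift.  Process time is not part of
#' the condition; it is the ninth model input and lives on the flattened
#' data points.
#'
#' Feeding and pH-shift days use the numeric sentinel \code{-1} for "none",
#' which keeps flattened feature tables purely numeric.
#'
#' @param ph_setpoint pH setpoint, in pH units (allowed range 6.6--7.6).
#' @param do_setpoint Dissolved-oxygen setpoint, \% air saturation (20--100).
#' @param vcd0 Inoculation viable cell density, 1e6 cells/mL (> 0).
#' @param glc_start Starting glucose concentration, g/L.
#' @param gln_start Starting glutamine concentration, mM.
#' @param glc_feed_target Glucose top-up target from day 5 on, g/L
#'   (0 = no glucose feed).
#' @param feed_start_day First day of daily nutrient feeding (1--5), or
#'   \code{-1} for a batch process without feeding.
#' @param ph_shift_day Day on which the pH setpoint is raised once and held
#'   (0--5), or \code{-1} for no shift.
#' @param ph_shift_value pH setpoint after the shift, in pH units.
#'
#' @return An object of class \code{cho_condition} (a named list).
#' @examples
#' std_condition()
#' process_condition(ph_setpoint = 7.4, do_setpoint = 40, vcd0 = 0.5,
#'                   glc_start = 8, gln_start = 12, glc_feed_target = 9,
#'                   feed_start_day = 1)
#' @export
process_condition <- function(ph_setpoint = 7.15, do_setpoint = 60, vcd0 = 0.3,
                              glc_start = 6, gln_start = 6, glc_feed_target = 5,
                              feed_start_day = 3, ph_shift_day = -1L,
                              ph_shift_value = 7.3) {
  cond <- list(
    ph_setpoint = as.numeric(ph_setpoint),
    do_setpoint = as.numeric(do_setpoint),
    vcd0 = as.numeric(vcd0),
    glc_start = as.numeric(glc_start),
    gln_start = as.numeric(gln_start),
    glc_feed_target = as.numeric(glc_feed_target),
    feed_start_day = as.integer(round(feed_start_day)),
    ph_shift_day = as.integer(round(ph_shift_day)),
    ph_shift_value = as.numeric(ph_shift_value)
  )
  class(cond) <- "cho_condition"
  validate_condition(cond)
  cond
}

validate_condition <- function(cond) {
  with_field <- function(ok, msg) if (!ok) stop_choopt("invalid condition: %s", msg)
  with_field(is_number(cond$ph_setpoint) && cond$ph_setpoint >= 6.6 && cond$ph_setpoint <= 7.6,
             "ph_setpoint must lie in [6.6, 7.6]")
  with_field(is_number(cond$do_setpoint) && cond$do_setpoint >= 20 && cond$do_setpoint <= 100,
             "do_setpoint must lie in [20, 100]")
  with_field(is_number(cond$vcd0) && cond$vcd0 > 0, "vcd0 must be > 0")
  with_field(is_number(cond$glc_start) && cond$glc_start >= 0, "glc_start must be >= 0")
  with_field(is_number(cond$gln_start) && cond$gln_start >= 0, "gln_start must be >= 0")
  with_field(is_number(cond$glc_feed_target) && cond$glc_feed_target >= 0,
             "glc_feed_target must be >= 0")
  with_field(cond$feed_start_day %in% c(-1L, 1:5),
             "feed_start_day must be -1 (batch) or a day in 1..5")
  with_field(cond$ph_shift_day %in% c(-1L, 0:5),
             "ph_shift_day must be -1 (no shift) or a day in 0..5")
  with_field(is_number(cond$ph_shift_value) && cond$ph_shift_value >= 6.6 &&
               cond$ph_shift_value <= 7.6,
             "ph_shift_value must lie in [6.6, 7.6]")
  invisible(cond)
}

#' @rdname process_condition
#' @export
std_condition <- function() process_condition()

#' @export
print.cho_condition <- function(x, ...) {
  cat("<cho_condition>\n")
  cat(sprintf("  pH %.2f / DO %.0f%% | VCD0 %.2f | Glc %.1f g/L, Gln %.1f mM\n",
              x$ph_setpoint, x$do_setpoint, x$vcd0, x$glc_start, x$gln_start))
  feed <- if (x$feed_start_day == -1L) "batch (no feed)" else
    sprintf("feed from day %d, Glc top-up to %.0f g/L", x$feed_start_day, x$glc_feed_target)
  shift <- if (x$ph_shift_day == -1L) "no pH shift" else
    sprintf("pH shift to %.2f on day %d", x$ph_shift_value, x$ph_shift_day)
  cat("  ", feed, " | ", shift, "\n", sep = "")
  invisible(x)
}

#' Build the deterministic condition lists of the experimental designs
#'
#' Reconstructs the condition groups of the study dataset: the standard
#' triplicate, a two-factor central composite circumscribed (CCC) design over
#' pH and DO, pH-shift runs, feed-timing and medium variations, stressful
#' high-pH / low-glutamine combinations, a duplicated three-factor
#' full-factorial design (feed start day, inoculation density, starting
#' glutamine), and glucose-feed variations.  \code{FULL_58} concatenates all
#' groups into the 58-condition design (3 standard + 55 varied runs).
#'
#' @param kind Design label, one of \code{"STD"}, \code{"CCC_PH_DO"},
#'   \code{"PH_SHIFT"}, \code{"FEED_MEDIA"}, \code{"EXTREME_COMBOS"},
#'   \code{"FACTORIAL_3"}, \code{"GLC_VARIATION"}, \code{"FULL_58"}.
#' @param ranges For \code{CCC_PH_DO}: a list with elements \code{ph} and
#'   \code{do}, each \code{c(min, max)} giving the axial (outermost) levels.
#'   Defaults: pH in [6.8, 7.5], DO in [20, 100].
#'
#' @return A named list of \code{cho_condition} objects; names are design
#'   labels carried into run metadata.
#' @examples
#' length(build_design("CCC_PH_DO"))  # 4 factorial + 4 axial + 1 center
#' length(build_design("FULL_58"))    # 58
#' @export
build_design <- function(kind, ranges = NULL) {
  kinds <- c("STD", "CCC_PH_DO", "PH_SHIFT", "FEED_MEDIA", "EXTREME_COMBOS",
             "FACTORIAL_3", "GLC_VARIATION", "FULL_58")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    stop_choopt("unknown design kind '%s'; expected one of: %s",
                paste(kind, collapse = ","), paste(kinds, collapse = ", "))
  }
  switch(kind,
    STD = {
      out <- replicate(3, std_condition(), simplify = FALSE)
      names(out) <- paste0("STD_", 1:3)
      out
    },
    CCC_PH_DO = design_ccc_ph_do(ranges),
    PH_SHIFT = {
      days <- c(0L, 3L, 4L, 5L)
      out <- list()
      for (d in days) {
        for (rep in 1:2) {
          out[[sprintf("PHSHIFT_d%d_%d", d, rep)]] <-
            process_condition(ph_setpoint = 7.1, ph_shift_day = d, ph_shift_value = 7.3)
        }
      }
      out
    },
    FEED_MEDIA = design_feed_media(),
    EXTREME_COMBOS = {
      tab <- data.frame(
        ph = c(7.4, 7.3, 7.35, 7.35), do = c(90, 90, 90, 90),
        glc = c(6.8, 6, 6, 6), gln = c(1, 1, 1, 2)
      )
      out <- lapply(seq_len(nrow(tab)), function(i) {
        process_condition(ph_setpoint = tab$ph[i], do_setpoint = tab$do[i],
                          glc_start = tab$glc[i], gln_start = tab$gln[i])
      })
      names(out) <- paste0("EXTREME_", seq_len(nrow(tab)))
      out
    },
    FACTORIAL_3 = {
      grid <- expand.grid(feed = c(1L, 5L), vcd0 = c(0.1, 0.5), gln = c(6, 12))
      out <- list()
      for (i in seq_len(nrow(grid))) {
        for (rep in 1:2) {
          out[[sprintf("FACT3_f%d_v%.1f_g%d_%d", grid$feed[i], grid$vcd0[i],
                       grid$gln[i], rep)]] <-
            process_condition(feed_start_day = grid$feed[i], vcd0 = grid$vcd0[i],
                              gln_start = grid$gln[i])
        }
      }
      out
    },
    GLC_VARIATION = {
      out <- list()
      for (rep in 1:3) {
        out[[paste0("GLCMINUS_", rep)]] <- process_condition(glc_feed_target = 0)
      }
      for (rep in 1:3) {
        out[[paste0("GLCPLUS_", rep)]] <- process_condition(glc_feed_target = 9)
      }
      out
    },
    FULL_58 = {
      out <- c(build_design("STD"), build_design("CCC_PH_DO", ranges),
               build_design("PH_SHIFT"), build_design("FEED_MEDIA"),
               build_design("EXTREME_COMBOS"), build_design("FACTORIAL_3"),
               build_design("GLC_VARIATION"))
      stopifnot(length(out) == 58L)
      out
    }
  )
}

design_ccc_ph_do <- function(ranges = NULL) {
  if (is.null(ranges)) ranges <- list(ph = c(6.8, 7.5), do = c(20, 100))
  for (f in c("ph", "do")) {
    if (is.null(ranges[[f]]) || length(ranges[[f]]) != 2L || diff(ranges[[f]]) <= 0) {
      stop_choopt("CCC ranges$%s must be c(min, max) with min < max", f)
    }
  }
  # axial points sit at the supplied bounds; factorial points at
  # center +/- half-range / sqrt(2) (rotatable alpha for two factors)
  ph_c <- mean(ranges$ph); do_c <- mean(ranges$do)
  ph_f <- diff(ranges$ph) / 2 / sqrt(2)
  do_f <- diff(ranges$do) / 2 / sqrt(2)
  pts <- rbind(
    expand.grid(ph = ph_c + c(-ph_f, ph_f), do = do_c + c(-do_f, do_f)),
    data.frame(ph = c(ranges$ph, ph_c, ph_c), do = c(do_c, do_c, ranges$do)),
    data.frame(ph = ph_c, do = do_c)
  )
  labels <- c(paste0("CCC_f", 1:4), paste0("CCC_a", 1:4), "CCC_c")
  out <- lapply(seq_len(nrow(pts)), function(i) {
    process_condition(ph_setpoint = round(pts$ph[i], 3), do_setpoint = round(pts$do[i], 1))
  })
  names(out) <- labels
  out
}

design_feed_media <- function() {
  out <- list()
  # batch (triplicate), batch with richer medium, higher Gln / Glc starts,
  # and shifted feeding start days
  for (rep in 1:3) {
    out[[paste0("BATCH_", rep)]] <-
      process_condition(feed_start_day = -1L, glc_feed_target = 0)
  }
  out[["BATCH_MEDIUM"]] <-
    process_condition(feed_start_day = -1L, glc_feed_target = 0, glc_start = 7.5)
  out[["GLN_9"]] <- process_condition(gln_start = 9)
  out[["GLN_12"]] <- process_condition(gln_start = 12)
  out[["GLC_9"]] <- process_condition(glc_start = 9)
  out[["GLC_12"]] <- process_condition(glc_start = 12)
  for (d in c(1L, 2L, 4L, 5L)) {
    out[[paste0("FEEDSTART_", d)]] <- process_condition(feed_start_day = d)
  }
  out
}
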