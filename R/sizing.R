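#' Round half away from zero
#'
#' Tabulated punch sizes are printed at 2 decimals with ties rounded away
#' from zero (so 6.125 prints as 6.13), unlike base `round()`'s
#' round-half-even. Exposed because the table-generation and
#' recommendation paths must agree on the convention.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return `x` rounded half-away-from-zero.
#' @examples
#' round_half_up(6.125)   # 6.13
#' round(6.125, 2)        # 6.12 under round-half-even
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Snap a size to the available punch step grid
#'
#' Punches and trephines come in discrete steps (0.25 mm clinically); the
#' computed arc length rarely lands on one. `snap_to_step()` maps a size to
#' a multiple of `step` under one of three policies:
#' \describe{
#'   \item{`"nearest-up-on-tie"`}{nearest multiple; exact midpoints go up.
#'     The default: the failure mode (membrane folds) comes from
#'     undersizing, so ties resolve to the larger punch.}
#'   \item{`"nearest-down-on-tie"`}{nearest multiple; midpoints go down.}
#'   \item{`"always-up"`}{smallest multiple >= the size (never undersize).}
#' }
#' Ties and grid membership are detected with a small relative tolerance so
#' snapping an already-snapped size is a no-op.
#'
#' @param size Size in mm (positive scalar).
#' @param step Grid granularity in mm (default 0.25).
#' @param policy One of the policies above.
#' @return A multiple of `step`, in mm.
#' @examples
#' snap_to_step(7.45)                       # 7.50
#' snap_to_step(6.40)                       # 6.50 (0.10 above vs 0.15 below)
#' snap_to_step(6.125, policy = "always-up") # 6.25
#' @export
snap_to_step <- function(size, step = STEP_DEFAULT,
                         policy = c("nearest-up-on-tie",
                                    "nearest-down-on-tie",
                                    "always-up")) {
  check_positive_scalar(size, "size")
  check_positive_scalar(step, "step")
  policy <- match.arg(policy)
  k <- size / step
  eps <- REL_TOL * max(1, k)
  lo <- floor(k + eps)          # treat near-integers as on-grid
  frac <- k - lo
  n <- switch(policy,
    "nearest-up-on-tie"   = if (frac >= 0.5 - eps) lo + 1 else lo,
    "nearest-down-on-tie" = if (frac >  0.5 + eps) lo + 1 else lo,
    "always-up"           = if (frac >  eps)       lo + 1 else lo
  )
  n * step
}

#' Recommend a donor punch size
#'
#' Computes the Descemet's membrane arc length for the given cornea and
#' trephine, rounds it to the 2-decimal table convention, and snaps it to
#' the available punch step grid. A donor button of this size matches the
#' membrane arc on the recipient bed and avoids fold-inducing undersizing.
#'
#' @inheritParams dm_arc_length
#' @param step Punch availability granularity in mm (default 0.25).
#' @param snap_policy Tie/rounding policy, see [snap_to_step()].
#' @return An object of class `punch_recommendation` with fields
#'   `exact_size` (unrounded arc, mm), `table_size` (2-decimal, mm),
#'   `snapped_size` (on the step grid, mm), `step`, `snap_policy`,
#'   `keratometry`, `trephine` and `kindex`.
#' @examples
#' recommend_punch(55, 7)    # table 7.45, snapped 7.50
#' recommend_punch(65, 6)    # table 6.40, snapped 6.50
#' @export
recommend_punch <- function(keratometry, trephine, kindex = KINDEX_DEFAULT,
                            step = STEP_DEFAULT,
                            snap_policy = c("nearest-up-on-tie",
                                            "nearest-down-on-tie",
                                            "always-up"),
                            warn = TRUE) {
  snap_policy <- match.arg(snap_policy)
  exact <- dm_arc_length(keratometry, trephine, kindex, warn = warn)
  structure(
    list(exact_size = exact,
         table_size = round_half_up(exact, 2),
         snapped_size = snap_to_step(exact, step, snap_policy),
         step = step, snap_policy = snap_policy,
         keratometry = keratometry, trephine = trephine, kindex = kindex),
    class = "punch_recommendation"
  )
}

#' @export
print.punch_recommendation <- function(x, ...) {
  cat(sprintf("Donor punch recommendation (K = %g D, trephine %.2f mm)\n",
              x$keratometry, x$trephine))
  cat(sprintf("  DM arc length : %.4f mm (table value %.2f mm)\n",
              x$exact_size, x$table_size))
  cat(sprintf("  snapped punch : %.2f mm (step %.2f mm, policy %s)\n",
              x$snapped_size, x$step, x$snap_policy))
  invisible(x)
}

#' Assess membrane-to-graft mismatch and fold risk
#'
#' Compares the Descemet's membrane arc length against a chosen punch size.
#' A positive mismatch (membrane longer than graft) flags fold risk: the
#' excess membrane wrinkles under the sutured graft. The threshold is
#' strictly zero by default; a tolerance can be supplied if a surgeon
#' accepts a small excess.
#'
#' @inheritParams recommend_punch
#' @param punch Chosen donor punch size in mm.
#' @param threshold Mismatch (mm) above which fold risk is flagged
#'   (default 0: any positive mismatch).
#' @return An object of class `mismatch_report` with fields `dm_arc` (mm),
#'   `punch` (mm), `mismatch` (signed, `dm_arc - punch`, mm) and
#'   `fold_risk` (logical).
#' @examples
#' assess_mismatch(62, 7.75, punch = 7.75)  # mismatch ~ +0.87, fold risk
#' assess_mismatch(62, 7.75, punch = 8.75)  # oversized graft, no fold risk
#' @export
assess_mismatch <- function(keratometry, trephine, punch,
                            kindex = KINDEX_DEFAULT, threshold = 0,
                            warn = TRUE) {
  check_positive_scalar(punch, "punch")
  arc <- dm_arc_length(keratometry, trephine, kindex, warn = warn)
  mismatch <- arc - punch
  structure(
    list(dm_arc = arc, punch = punch, mismatch = mismatch,
         fold_risk = mismatch > threshold, threshold = threshold,
         keratometry = keratometry, trephine = trephine),
    class = "mismatch_report"
  )
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(sprintf("Mismatch report (K = %g D, trephine %.2f mm, punch %.2f mm)\n",
              x$keratometry, x$trephine, x$punch))
  cat(sprintf("  DM arc %.4f mm, mismatch %+.4f mm -> fold risk: %s\n",
              x$dm_arc, x$mismatch, if (x$fold_risk) "YES" else "no"))
  invisible(x)
}

#' Trephine diameter needed for a target punch size
#'
#' Inverse of the forward model: given the punch size in stock, find the
#' trephine whose membrane arc equals it. Inverting `x = r * alpha` with
#' chord `a = 2 r sin(alpha / 2)` gives
#' `a = 2 r sin(x / (2 r))`. The target arc cannot exceed a semicircle's
#' arc (`pi * r`), beyond which no chord reproduces it.
#'
#' @inheritParams diopters_to_radius
#' @param target_punch Target punch size (arc length to reproduce), mm.
#' @return Trephine diameter in mm; round-trips through [dm_arc_length()]
#'   to the target within 1e-9 mm.
#' @examples
#' trephine_for_punch(45, 6.1727)  # ~ 6.00 mm
#' @export
trephine_for_punch <- function(keratometry, target_punch,
                               kindex = KINDEX_DEFAULT) {
  check_positive_scalar(target_punch, "target_punch")
  r <- diopters_to_radius(keratometry, kindex)
  if (target_punch > pi * r * (1 + REL_TOL)) {
    stop(sprintf(
      "target punch %g mm exceeds the semicircular arc limit %.4f mm for r = %.4f mm",
      target_punch, pi * r, r), call. = FALSE)
  }
  2 * r * sin(min(target_punch, pi * r) / (2 * r))
}
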