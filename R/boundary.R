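#' Partition sites into specific and non-specific sets by Ri
#'
#' Sites with individual information at or above the threshold (default
#' 0 bits) are classed specific; below, non-specific. Ties at the
#' threshold go to the specific set (the conventional "Ri >= 0" rule).
#'
#' @param ri named numeric vector of Ri scores (bits).
#' @param threshold classification threshold in bits.
#' @return A list with character vectors `specific` and `nonspecific`
#'   (disjoint, exhaustive).
#' @export
partition_by_ri <- function(ri, threshold = 0) {
  spec <- names(ri)[ri >= threshold]
  list(specific = spec,
       nonspecific = setdiff(names(ri), spec))
}

#' Ordinary least-squares line through (Ri, ddG) points
#'
#' Plain OLS of binding energy on predicted information, as used for the
#' two-branch boundary fit.
#'
#' @param ri numeric predictor (bits).
#' @param ddg numeric response (kJ/mol).
#' @param which label recorded on the fit: "specific" or "nonspecific".
#' @return A list of class `ri_line`: `slope` (kJ/mol per bit),
#'   `intercept` (kJ/mol at Ri = 0), `r2`, `n_points`, `which`.
#' @export
fit_line <- function(ri, ddg, which = c("specific", "nonspecific")) {
  which <- match.arg(which)
  if (length(ri) < 2L || length(ri) != length(ddg))
    stop("need >= 2 paired (ri, ddg) points")
  if (stats::var(ri) <= .Machine$double.eps * max(1, mean(ri)^2))
    stop("degenerate fit: all Ri values are (numerically) equal")
  fit <- stats::lm(ddg ~ ri)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ddg - mean(ddg))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = max(0, min(1, r2)),
                 n_points = length(ri),
                 which = which),
            class = "ri_line")
}

#' @export
print.ri_line <- function(x, ...) {
  cat(sprintf("%s line: ddG = %.4g %+.4g Ri  (r2 = %.3f, n = %d)\n",
              x$which, x$intercept, x$slope, x$r2, x$n_points))
  invisible(x)
}

#' Non-specific binding energy from the two regression lines
#'
#' Method `"intersection"` takes the ddG value at the crossing point of
#' the specific- and non-specific-site lines; method `"ri0-intercept"`
#' evaluates the specific-site line at Ri = 0 bits. When the lines are
#' (numerically) parallel, `"intersection"` falls back to
#' `"ri0-intercept"` with a warning.
#'
#' @param fit_pos,fit_neg [fit_line()] fits to the specific (Ri >= 0) and
#'   non-specific (Ri < 0) sites.
#' @param method `"intersection"` or `"ri0-intercept"`.
#' @return A list: `dg_ns` (kJ/mol), `ri_at_boundary` (bits; NA for the
#'   intercept method), `method` actually used.
#' @export
nonspecific_energy <- function(fit_pos, fit_neg,
                               method = c("intersection", "ri0-intercept")) {
  method <- match.arg(method)
  if (missing(fit_pos) || is.null(fit_pos) ||
      missing(fit_neg) || is.null(fit_neg))
    stop("both regression fits are required")
  if (method == "intersection") {
    dslope <- fit_pos$slope - fit_neg$slope
    scale <- max(abs(c(fit_pos$slope, fit_neg$slope, 1)))
    if (abs(dslope) < 1e-12 * scale) {
      warning("regression lines are parallel; falling back to the ",
              "Ri = 0 intercept of the specific line")
      method <- "ri0-intercept"
    } else {
      x <- (fit_neg$intercept - fit_pos$intercept) / dslope
      return(list(dg_ns = fit_pos$slope * x + fit_pos$intercept,
                  ri_at_boundary = x, method = "intersection"))
    }
  }
  list(dg_ns = fit_pos$intercept, ri_at_boundary = NA_real_,
       method = "ri0-intercept")
}

#' Fit the specific/non-specific binding boundary
#'
#' The central estimator of the package: given each site's predicted
#' individual information Ri (bits) and measured relative binding energy
#' ddG (kJ/mol), sites are partitioned at the Ri threshold, an OLS line
#' is fitted to each branch, and the non-specific binding energy dGns is
#' derived from the pair of lines. For an informative additive model the
#' specific branch has negative slope (higher information, tighter
#' binding) while the non-specific branch is nearly flat at the binding
#' floor; dGns estimates the height of that floor above the strongest
#' site.
#'
#' The fit is flagged unreliable when the specific branch has fewer than
#' 4 points or r2 below 0.3 (a nearly non-specific binder gives no
#' trustworthy boundary).
#'
#' @param ri named numeric vector of Ri scores (bits), one per site.
#' @param ddg named numeric vector of measured ddG (kJ/mol) over the same
#'   sites (any order; matched by name).
#' @param threshold partition threshold in bits (default 0).
#' @param method dGns derivation, see [nonspecific_energy()].
#' @return An object of class `boundary_fit` with components `fit_pos`,
#'   `fit_neg` ([fit_line()] objects), `dg_ns`, `ri_at_boundary`,
#'   `method`, `reliable`, `threshold`, and `data` (site/ri/ddg/class).
#'   Supports `print()`, `summary()`, `coef()`, `predict()` and `plot()`.
#' @examples
#' fm <- frequency_matrix(rbind(c(.7, .1, .1, .1), c(.1, .7, .1, .1)))
#' rm <- ri_weights(fm)
#' ri <- ri_all_sites(rm)
#' ddg <- pmin(3 - 1.7 * ri, 4)  # linear toy energies with a flat floor
#' b <- specificity_boundary(ri, ddg)
#' coef(b)
#' @export
specificity_boundary <- function(ri, ddg, threshold = 0,
                                 method = c("intersection",
                                            "ri0-intercept")) {
  method <- match.arg(method)
  if (is.null(names(ri)) || is.null(names(ddg)))
    stop("ri and ddg must be named by site")
  if (!setequal(names(ri), names(ddg)))
    stop("ri and ddg must cover the same site universe")
  ddg <- ddg[names(ri)]
  part <- partition_by_ri(ri, threshold)
  if (length(part$specific) < 2L || length(part$nonspecific) < 2L)
    stop("need at least 2 sites on each side of the threshold")
  fit_pos <- fit_line(ri[part$specific], ddg[part$specific], "specific")
  fit_neg <- fit_line(ri[part$nonspecific], ddg[part$nonspecific],
                      "nonspecific")
  ns <- nonspecific_energy(fit_pos, fit_neg, method)
  structure(list(fit_pos = fit_pos, fit_neg = fit_neg,
                 dg_ns = ns$dg_ns, ri_at_boundary = ns$ri_at_boundary,
                 method = ns$method, threshold = threshold,
                 reliable = fit_pos$n_points >= 4L && fit_pos$r2 >= 0.3,
                 data = data.frame(site = names(ri),
                                   ri = as.numeric(ri),
                                   ddg = as.numeric(ddg),
                                   class = ifelse(names(ri) %in%
                                                    part$specific,
                                                  "specific",
                                                  "nonspecific"),
                                   stringsAsFactors = FALSE)),
            class = "boundary_fit")
}

#' @export
print.boundary_fit <- function(x, ...) {
  cat("Specific/non-specific boundary fit\n")
  print(x$fit_pos)
  print(x$fit_neg)
  cat(sprintf("dGns = %.3f kJ/mol (%s)%s\n", x$dg_ns, x$method,
              if (!x$reliable) "  [flagged unreliable]" else ""))
  invisible(x)
}

#' @export
summary.boundary_fit <- function(object, ...) {
  out <- list(dg_ns = object$dg_ns, method = object$method,
              reliable = object$reliable,
              n_specific = object$fit_pos$n_points,
              n_nonspecific = object$fit_neg$n_points,
              r2_specific = object$fit_pos$r2,
              r2_nonspecific = object$fit_neg$r2,
              slope_specific = object$fit_pos$slope,
              slope_nonspecific = object$fit_neg$slope)
  class(out) <- "summary.boundary_fit"
  out
}

#' @export
print.summary.boundary_fit <- function(x, ...) {
  cat(sprintf(paste0("dGns = %.3f kJ/mol (%s%s)\n",
                     "specific:     n = %d, slope = %.3f, r2 = %.3f\n",
                     "non-specific: n = %d, slope = %.3f, r2 = %.3f\n"),
              x$dg_ns, x$method,
              if (!x$reliable) ", unreliable" else "",
              x$n_specific, x$slope_specific, x$r2_specific,
              x$n_nonspecific, x$slope_nonspecific, x$r2_nonspecific))
  invisible(x)
}

#' @export
coef.boundary_fit <- function(object, ...) {
  c(dg_ns = object$dg_ns,
    slope_specific = object$fit_pos$slope,
    intercept_specific = object$fit_pos$intercept,
    slope_nonspecific = object$fit_neg$slope,
    intercept_nonspecific = object$fit_neg$intercept)
}

#' @export
#' @rdname specificity_boundary
#' @param object,x a `boundary_fit`.
#' @param newdata numeric vector of Ri values at which to predict ddG
#'   (each value is routed to its branch's line by the threshold).
#' @param ... unused.
predict.boundary_fit <- function(object, newdata, ...) {
  if (missing(newdata)) newdata <- object$data$ri
  pos <- newdata >= object$threshold
  ifelse(pos,
         object$fit_pos$intercept + object$fit_pos$slope * newdata,
         object$fit_neg$intercept + object$fit_neg$slope * newdata)
}

#' @export
#' @rdname specificity_boundary
plot.boundary_fit <- function(x, ...) {
  d <- x$data
  cols <- ifelse(d$class == "specific", "#2166ac", "#b2182b")
  graphics::plot(d$ri, d$ddg, col = cols, pch = 19,
                 xlab = "Ri (bits)",
                 ylab = expression(Delta * Delta * G ~ "(kJ/mol)"), ...)
  graphics::abline(x$fit_pos$intercept, x$fit_pos$slope, col = "#2166ac")
  graphics::abline(x$fit_neg$intercept, x$fit_neg$slope, col = "#b2182b")
  graphics::abline(h = x$dg_ns, lty = 3)
  graphics::legend("topright", bty = "n",
                   legend = c(sprintf("specific (r2 = %.2f)", x$fit_pos$r2),
                              sprintf("non-specific (r2 = %.2f)",
                                      x$fit_neg$r2),
                              sprintf("dGns = %.2f kJ/mol", x$dg_ns)),
                   col = c("#2166ac", "#b2182b", "black"),
                   pch = c(19, 19, NA), lty = c(1, 1, 3))
  invisible(x)
}

#' Per-site report table behind a boundary fit
#'
#' @param x a [specificity_boundary()] fit.
#' @return Data frame (site, ri, ddg, class) ordered by decreasing Ri.
#' @export
boundary_report <- function(x) {
  stopifnot(inherits(x, "boundary_fit"))
  x$data[order(-x$data$ri), , drop = FALSE]
}
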