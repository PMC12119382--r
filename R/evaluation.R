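# Agreement statistics for comparing two sets of plans (tool vs tool, or
# tool vs phantom ground truth): per-case Euclidean distances, per-axis
# deviations with paired t-tests, and Bland-Altman limits of agreement.
# Differences are always computed as A - B; SDs use the n-1 denominator and
# 95% CIs the t distribution.

.mean_sd_ci <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  half <- if (n > 1 && s > 0) stats::qt(0.975, n - 1) * s / sqrt(n) else 0
  c(mean = m, sd = s, ci_low = m - half, ci_high = m + half, n = n)
}

.paired_t <- function(d) {
  if (length(d) < 2 || stats::sd(d) == 0)
    return(c(t = NA_real_, p = NA_real_, df = length(d) - 1))
  tt <- stats::t.test(d)
  c(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Agreement between two paired point sets
#'
#' For case-paired Leksell coordinates from two methods, computes the
#' per-case Euclidean distance, the per-axis signed differences (A - B) and
#' absolute deviations, their means, SDs and t-based 95% CIs, and a paired
#' t-test per axis on the signed differences. A degenerate axis (all
#' differences identical) reports `NA` for the t statistic.
#'
#' @param a,b n x 3 matrices of paired points (n >= 2), same units.
#' @param axes Axis names for the report, default X, Y, Z.
#' @return An object of class `point_agreement`: list with `distances`,
#'   `distance_stats`, `signed_diff` (n x 3), `per_axis` (data frame with
#'   abs-deviation stats and paired t per axis).
#' @export
point_agreement <- function(a, b, axes = c("X", "Y", "Z")) {
  a <- .as_points(a, "set A"); b <- .as_points(b, "set B")
  if (nrow(a) != nrow(b))
    stop("point_agreement: sets must be case-paired (equal counts)",
         call. = FALSE)
  if (nrow(a) < 2)
    stop("point_agreement: at least 2 paired cases are required",
         call. = FALSE)
  d <- a - b
  dist <- sqrt(rowSums(d^2))
  per_axis <- do.call(rbind, lapply(1:3, function(ax) {
    stats_abs <- .mean_sd_ci(abs(d[, ax]))
    tt <- .paired_t(d[, ax])
    data.frame(axis = axes[ax],
               abs_mean = stats_abs[["mean"]], abs_sd = stats_abs[["sd"]],
               abs_ci_low = stats_abs[["ci_low"]],
               abs_ci_high = stats_abs[["ci_high"]],
               signed_mean = mean(d[, ax]),
               t = tt[["t"]], p = tt[["p"]])
  }))
  structure(list(distances = dist,
                 distance_stats = .mean_sd_ci(dist),
                 signed_diff = d,
                 per_axis = per_axis),
            class = "point_agreement")
}

#' Agreement between two paired angle series
#'
#' Signed (A - B) and absolute deviations with mean, SD, t-based 95% CI and
#' a paired t-test on the signed deviations.
#'
#' @param a,b Numeric vectors of paired angles (degrees), length >= 2.
#' @return An object of class `angle_agreement`: list with `signed`, `abs`,
#'   `abs_stats`, `signed_stats`, `t`, `p`.
#' @export
angle_agreement <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b))
    stop("angle_agreement: series must be paired (equal lengths)",
         call. = FALSE)
  if (length(a) < 2)
    stop("angle_agreement: at least 2 paired cases are required",
         call. = FALSE)
  d <- a - b
  tt <- .paired_t(d)
  structure(list(signed = d, abs = abs(d),
                 abs_stats = .mean_sd_ci(abs(d)),
                 signed_stats = .mean_sd_ci(d),
                 t = tt[["t"]], p = tt[["p"]]),
            class = "angle_agreement")
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Bias is the mean difference; the limits are bias +/- 1.96 times the
#' sample SD (n - 1 denominator) of the differences.
#'
#' @param diffs Numeric vector of paired differences (n >= 2).
#' @return List with `bias`, `loa_low`, `loa_high`, `sd`, `n`,
#'   `sd_denominator` (`"n-1"`, recorded so the convention is explicit).
#' @export
bland_altman <- function(diffs) {
  stopifnot(is.numeric(diffs))
  if (length(diffs) < 2)
    stop("bland_altman: at least 2 differences are required", call. = FALSE)
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, n = length(diffs), sd_denominator = "n-1")
}

#' Full agreement report for two plan sets
#'
#' Combines [point_agreement()] on the Leksell target coordinates with
#' [angle_agreement()] and [bland_altman()] on the arc and ring angles.
#' Differences are A - B throughout.
#'
#' @param plans_a,plans_b Data frames with columns `case`, `x`, `y`, `z`
#'   (Leksell mm) and optionally `arc`, `ring` (degrees), case-paired by the
#'   `case` column.
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(plans_a, plans_b) {
  need <- c("case", "x", "y", "z")
  stopifnot(all(need %in% names(plans_a)), all(need %in% names(plans_b)))
  if (nrow(plans_a) != nrow(plans_b) ||
      !setequal(plans_a$case, plans_b$case) || anyDuplicated(plans_a$case))
    stop("agreement_report: case IDs must pair one-to-one", call. = FALSE)
  plans_b <- plans_b[match(plans_a$case, plans_b$case), ]
  pts <- point_agreement(as.matrix(plans_a[, c("x", "y", "z")]),
                         as.matrix(plans_b[, c("x", "y", "z")]))
  out <- list(sign_convention = "A - B", n = nrow(plans_a), points = pts)
  for (ang in c("arc", "ring")) {
    if (ang %in% names(plans_a) && ang %in% names(plans_b)) {
      aa <- angle_agreement(plans_a[[ang]], plans_b[[ang]])
      out[[ang]] <- list(agreement = aa,
                         bland_altman = bland_altman(aa$signed))
    }
  }
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (differences %s, n = %d)\n",
              x$sign_convention, x$n))
  ds <- x$points$distance_stats
  cat(sprintf("  target Euclidean distance: %.3f +/- %.3f mm (95%% CI %.3f-%.3f)\n",
              ds[["mean"]], ds[["sd"]], ds[["ci_low"]], ds[["ci_high"]]))
  pa <- x$points$per_axis
  for (r in seq_len(nrow(pa)))
    cat(sprintf("  |d%s|: %.3f +/- %.3f mm (t = %.2f, p = %.3f)\n",
                pa$axis[r], pa$abs_mean[r], pa$abs_sd[r], pa$t[r], pa$p[r]))
  for (ang in c("arc", "ring")) {
    if (is.null(x[[ang]])) next
    st <- x[[ang]]$agreement$abs_stats
    ba <- x[[ang]]$bland_altman
    cat(sprintf("  %s: |dev| %.2f +/- %.2f deg; bias %.2f deg, LoA %.2f to %.2f deg\n",
                ang, st[["mean"]], st[["sd"]], ba$bias, ba$loa_low,
                ba$loa_high))
  }
  invisible(x)
}

#' Write an agreement report as JSON (plus an optional text table)
#'
#' @param report An [agreement_report()].
#' @param path Output JSON path.
#' @param text_path Optional path for a human-readable table.
#' @return `path`, invisibly.
#' @export
write_agreement_json <- function(report, path, text_path = NULL) {
  stopifnot(inherits(report, "agreement_report"))
  to_list <- function(x) as.list(x)
  out <- list(sign_convention = report$sign_convention,
              sd_denominator = "n-1",
              n = report$n,
              target = list(
                distances_mm = report$points$distances,
                stats = to_list(report$points$distance_stats),
                per_axis = report$points$per_axis))
  for (ang in c("arc", "ring")) {
    if (is.null(report[[ang]])) next
    out[[ang]] <- list(abs_stats = to_list(report[[ang]]$agreement$abs_stats),
                       t = report[[ang]]$agreement$t,
                       p = report[[ang]]$agreement$p,
                       bland_altman = report[[ang]]$bland_altman)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(path)
}
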