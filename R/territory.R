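#' Mean parameter value over a coronary territory
#'
#' Mean of a fitted map over the valid pixels of one territory.
#'
#' @param map A `parameter_map`.
#' @param labels Integer territory label array (see [territory_levels()]).
#' @param territory Territory name, e.g. `"LCX"`.
#' @return A list: `mean`, `sd`, `n_valid`, `territory`.
#' @export
roi_mean <- function(map, labels, territory) {
  stopifnot(inherits(map, "parameter_map"))
  labels <- as.array(labels)
  if (!identical(dim(labels), dim(map$values)))
    stop_ironmap("labels and map geometry differ", "ironmap_geometry_mismatch")
  code <- territory_code(territory)
  sel <- labels == code
  if (!any(sel))
    stop_ironmap(sprintf("territory '%s' absent from labels", territory),
                 "ironmap_bad_territory")
  sel <- sel & map$valid
  if (!any(sel))
    stop_ironmap(sprintf("no valid pixels in territory '%s'", territory),
                 "ironmap_no_valid_pixels")
  v <- map$values[sel]
  list(mean = mean(v), sd = stats::sd(v), n_valid = length(v),
       territory = territory)
}

#' Pre/post-contrast delta-R2* per coronary territory
#'
#' The per-territory change in mean R2* from before to after intracoronary
#' injection of the iron-oxide contrast agent: the macroscopic field
#' contribution and any reperfusion-related R2* elevation are common to both
#' time points, so the difference isolates the contrast deposition. Means
#' are taken over the intersection of the pre and post validity masks.
#'
#' Maps may be given as single `parameter_map`s or as lists of maps (e.g.
#' basal/mid/apical short-axis slices, with matching label arrays); slices
#' are pooled per territory before averaging.
#'
#' @param pre,post R2* `parameter_map`(s) before/after injection.
#' @param labels Territory label array(s) matching the maps.
#' @param territories Which territories to report.
#' @return A `territory_report`: data frame with `territory`, `mean_pre`,
#'   `mean_post`, `delta` (exactly `mean_post - mean_pre`), `n_pixels`.
#' @export
delta_r2star <- function(pre, post, labels,
                         territories = c("LCX", "LAD", "RCA")) {
  pre_l <- if (inherits(pre, "parameter_map")) list(pre) else pre
  post_l <- if (inherits(post, "parameter_map")) list(post) else post
  lab_l <- if (is.list(labels) && !is.array(labels)) labels else list(labels)
  if (length(lab_l) == 1 && length(pre_l) > 1)
    lab_l <- rep(lab_l, length(pre_l))
  if (length(pre_l) != length(post_l) || length(pre_l) != length(lab_l))
    stop_ironmap("pre, post and labels must have matching slice counts",
                 "ironmap_geometry_mismatch")
  for (i in seq_along(pre_l)) {
    stopifnot(inherits(pre_l[[i]], "parameter_map"),
              inherits(post_l[[i]], "parameter_map"))
    if (pre_l[[i]]$kind != "R2star" || post_l[[i]]$kind != "R2star")
      stop_ironmap("delta_r2star requires R2star maps", "ironmap_bad_map")
    if (!identical(dim(pre_l[[i]]$values), dim(post_l[[i]]$values)) ||
        !identical(dim(pre_l[[i]]$values), dim(as.array(lab_l[[i]]))))
      stop_ironmap("pre/post/label geometry mismatch", "ironmap_geometry_mismatch")
  }

  rows <- lapply(territories, function(tn) {
    code <- territory_code(tn)
    vp <- c(); vq <- c()
    for (i in seq_along(pre_l)) {
      sel <- as.array(lab_l[[i]]) == code &
        pre_l[[i]]$valid & post_l[[i]]$valid
      vp <- c(vp, pre_l[[i]]$values[sel])
      vq <- c(vq, post_l[[i]]$values[sel])
    }
    if (!length(vp))
      stop_ironmap(sprintf("no jointly valid pixels in territory '%s'", tn),
                   "ironmap_no_valid_pixels")
    mp <- mean(vp); mq <- mean(vq)
    data.frame(territory = tn, mean_pre = mp, mean_post = mq,
               delta = mq - mp, n_pixels = length(vp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("territory_report", "data.frame")
  out
}

#' Fit a Gaussian to the histogram of a sample
#'
#' Builds a histogram and fits `a * exp(-(x - mu)^2 / (2*sigma^2))` to the
#' bin counts by nonlinear least squares (Levenberg-Marquardt), initialized
#' from the sample moments. This deliberately fits the histogram rather than
#' using the moments directly, matching how the normal distribution is fit
#' to R2* histograms in the ex vivo count-ratio statistic.
#'
#' @param values Numeric sample (e.g. valid R2* values over the myocardium).
#' @param binning `"fd"` for Freedman-Diaconis (default) or an integer bin
#'   count.
#' @return List: `mu`, `sigma`, `amplitude`, `breaks`, `counts`, `mids`.
#' @export
fit_gaussian_histogram <- function(values, binning = "fd") {
  values <- values[is.finite(values)]
  if (length(values) < 10)
    stop_ironmap("need at least 10 finite values", "ironmap_gaussian_fit")
  rng <- diff(range(values))
  if (rng <= .Machine$double.eps^0.5 * max(1, abs(mean(values)))) {
    # (numerically) constant sample: the histogram is a single spike, so the
    # fitted normal degenerates to mu = the common value, sigma = sample sd
    mu <- mean(values)
    w <- max(rng, .Machine$double.eps * max(1, abs(mu)))
    return(list(mu = mu, sigma = stats::sd(values), amplitude = length(values),
                breaks = c(mu - w, mu + w), counts = length(values), mids = mu))
  }
  breaks <- if (identical(binning, "fd")) {
    nb <- grDevices::nclass.FD(values)
    seq(min(values), max(values), length.out = max(nb, 4) + 1)
  } else {
    seq(min(values), max(values), length.out = as.integer(binning) + 1)
  }
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  start <- list(a = max(h$counts), mu = mean(values), s = stats::sd(values))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit))
    stop_ironmap("Gaussian fit to histogram failed",
                 "ironmap_gaussian_fit",
                 data = list(breaks = h$breaks, counts = h$counts))
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["s"]] == 0)
    stop_ironmap("Gaussian fit degenerate", "ironmap_gaussian_fit",
                 data = list(breaks = h$breaks, counts = h$counts))
  list(mu = cf[["mu"]], sigma = abs(cf[["s"]]), amplitude = cf[["a"]],
       breaks = h$breaks, counts = h$counts, mids = h$mids)
}

#' Ex vivo high-R2* pixel count-ratio statistic
#'
#' Quantifies focal iron deposition on an ex vivo R2* map: a normal
#' distribution is fitted to the histogram of R2* values over the whole LV
#' myocardium; every pixel strictly above `mu + 2*sigma` is counted in the
#' lesion and reference regions; counts are normalized by each region's
#' valid-pixel area, and the ratio lesion/reference is returned. In a heart
#' without focal deposition the ratio is close to 1; bound iron-oxide
#' particles in the lesion territory push it above 1.
#'
#' @param map An R2* `parameter_map`.
#' @param myocardium_mask Logical array: the whole LV myocardium over which
#'   the Gaussian is fitted (lesion pixels included).
#' @param labels Territory label array.
#' @param lesion,reference Territory names for numerator and denominator.
#' @param binning Histogram binning policy, see [fit_gaussian_histogram()].
#' @return A `count_ratio_result`: `mu`, `sigma`, `threshold`
#'   (`= mu + 2*sigma`), per-region counts and areas, normalized counts,
#'   `ratio`, and the histogram (`breaks`, `counts`).
#' @export
exvivo_count_ratio <- function(map, myocardium_mask, labels,
                               lesion = "LCX", reference = "LAD",
                               binning = "fd") {
  stopifnot(inherits(map, "parameter_map"))
  myocardium_mask <- as.array(myocardium_mask)
  labels <- as.array(labels)
  if (!identical(dim(myocardium_mask), dim(map$values)) ||
      !identical(dim(labels), dim(map$values)))
    stop_ironmap("mask/label geometry mismatch", "ironmap_geometry_mismatch")
  sel_lv <- myocardium_mask & map$valid
  if (sum(sel_lv) < 100)
    stop_ironmap("need >= 100 valid myocardial pixels", "ironmap_too_few_pixels")
  gfit <- fit_gaussian_histogram(map$values[sel_lv], binning)
  threshold <- gfit$mu + 2 * gfit$sigma

  region <- function(tn) {
    sel <- labels == territory_code(tn) & map$valid
    area <- sum(sel)
    if (area == 0)
      stop_ironmap(sprintf("no valid pixels in territory '%s'", tn),
                   "ironmap_no_valid_pixels")
    list(count = sum(map$values[sel] > threshold), area = area)
  }
  les <- region(lesion); ref <- region(reference)
  norm_les <- les$count / les$area
  norm_ref <- ref$count / ref$area
  structure(
    list(mu = gfit$mu, sigma = gfit$sigma, threshold = threshold,
         count_lesion = les$count, count_reference = ref$count,
         area_lesion = les$area, area_reference = ref$area,
         norm_lesion = norm_les, norm_reference = norm_ref,
         ratio = norm_les / norm_ref,
         lesion = lesion, reference = reference,
         histogram = list(breaks = gfit$breaks, counts = gfit$counts)),
    class = "count_ratio_result"
  )
}

#' @export
print.count_ratio_result <- function(x, ...) {
  cat(sprintf(
    "<count_ratio_result> mu = %.3g, sigma = %.3g, threshold = %.3g 1/s\n  %s: %d/%d px  %s: %d/%d px  ratio = %.4g\n",
    x$mu, x$sigma, x$threshold, x$lesion, x$count_lesion, x$area_lesion,
    x$reference, x$count_reference, x$area_reference, x$ratio))
  invisible(x)
}

#' Group comparison with standard tests
#'
#' Thin wrapper over the standard routines used for read-out comparisons:
#' Mann-Whitney U (`wilcox.test`), Student's t test, or one-way ANOVA
#' followed by Bonferroni-adjusted pairwise t tests (p multiplied by the
#' number of comparisons, capped at 1).
#'
#' @param groups Named list of numeric vectors (>= 2 observations each).
#' @param test `"mann_whitney"`, `"t"`, or `"anova_bonferroni"`.
#' @return Data frame with `comparison`, `statistic`, `p_value` (and
#'   `p_adjusted` for the ANOVA follow-up).
#' @export
compare_groups <- function(groups, test = c("mann_whitney", "t", "anova_bonferroni")) {
  test <- match.arg(test)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop_ironmap("each group needs >= 2 observations", "ironmap_bad_groups")
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  if (is.null(names(groups))) names(groups) <- nm

  if (test %in% c("mann_whitney", "t")) {
    if (length(groups) != 2)
      stop_ironmap("two-sample tests need exactly 2 groups", "ironmap_bad_groups")
    res <- if (test == "mann_whitney")
      suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE))
    else stats::t.test(groups[[1]], groups[[2]])
    return(data.frame(comparison = paste(nm[1], "vs", nm[2]),
                      statistic = unname(res$statistic),
                      p_value = res$p.value))
  }

  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(nm, vapply(groups, length, 1L)), levels = nm)
  av <- stats::aov(values ~ fac)
  p_overall <- summary(av)[[1]][["Pr(>F)"]][1]
  combs <- utils::combn(nm, 2, simplify = FALSE)
  rows <- lapply(combs, function(cc) {
    tt <- stats::t.test(groups[[cc[1]]], groups[[cc[2]]])
    data.frame(comparison = paste(cc[1], "vs", cc[2]),
               statistic = unname(tt$statistic), p_value = tt$p.value,
               p_adjusted = min(tt$p.value * length(combs), 1))
  })
  out <- do.call(rbind, rows)
  attr(out, "anova_p") <- p_overall
  out
}
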