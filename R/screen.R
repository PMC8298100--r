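# Vesicle-capture (knocksideways) screen statistics.
#
# Corerouting of a candidate Rab with a mitochondrially trapped construct is
# quantified per cell as the mitochondrial intensity ratio F_post / F_pre.
# Inference: Dunnett's many-to-one test against the fluorophore control,
# estimation statistics as mean differences with BCa bootstrap confidence
# intervals, per-screen Z-score matrices, and hierarchical clustering of Rab
# profiles across screens.

#' Mitochondrial intensity ratio of one cell
#'
#' Pools the pixels of all ROIs (10 ROIs of 10 x 10 px on the mitochondria in
#' the original protocol) and returns mean(post) / mean(pre). Pooling the
#' grand pixel mean is identical to averaging per-ROI means when all ROIs
#' have equal size.
#'
#' @param pre_image,post_image Numeric matrices of identical shape.
#' @param rois List of [roi()]s placed on the mitochondria.
#' @return The scalar ratio F_post / F_pre.
#' @export
mito_intensity_ratio <- function(pre_image, post_image, rois) {
  if (!identical(dim(pre_image), dim(post_image))) {
    stop("pre and post images must have identical shape", call. = FALSE)
  }
  rois <- as_roi_list(rois)
  pre_px <- post_px <- numeric(0)
  for (r in rois) {
    check_roi_inside(r, dim(pre_image))
    pre_px <- c(pre_px, pre_image[roi_rows(r), roi_cols(r)])
    post_px <- c(post_px, post_image[roi_rows(r), roi_cols(r)])
  }
  m_pre <- mean(pre_px)
  if (m_pre == 0) stop("pre-rapamycin ROI mean is zero; ratio undefined", call. = FALSE)
  mean(post_px) / m_pre
}

# --- Dunnett many-to-one test ----------------------------------------------

# P(max_i |T_i| <= q) for Dunnett statistics with correlation lambda_i
# lambda_j, pooled-variance df `df`. Evaluated as a double Gauss-Legendre
# quadrature over the shared control variate z and the pooled scale s (the s
# integral uses the exact scaled-chi density of sqrt(chisq_df / df)).
# Agrees with pt() to ~1e-13 in the single-comparison case.
pdunnett_abs <- function(q, lambda, df, n_nodes = 128) {
  if (q <= 0) return(0)
  gl <- gauss_legendre(n_nodes)
  zlim <- 9
  z <- gl$nodes * zlim
  wz <- gl$weights * zlim * dnorm(z)
  shi <- sqrt(qchisq(1 - 1e-13, df) / df)
  s <- (gl$nodes + 1) / 2 * shi
  ws <- gl$weights / 2 * shi * (2 * s * df * dchisq(df * s^2, df))
  total <- 0
  for (i in seq_along(s)) {
    p <- rep(1, length(z))
    for (l in lambda) {
      sl <- sqrt(1 - l^2)
      p <- p * (pnorm((q * s[i] - l * z) / sl) - pnorm((-q * s[i] - l * z) / sl))
    }
    total <- total + ws[i] * sum(wz * p)
  }
  min(max(total, 0), 1)
}

#' Dunnett critical value
#'
#' Two-sided critical value `q` with `P(max |T_i| <= q) = 1 - alpha` for
#' many-to-one comparisons against a control.
#'
#' @param ns Integer vector of group sizes for the treatment groups.
#' @param n_control Control group size.
#' @param alpha Family-wise error rate.
#' @param df Residual degrees of freedom (default: pooled,
#'   `sum(ns) + n_control - k - 1`).
#' @return The critical value.
#' @export
dunnett_critical <- function(ns, n_control, alpha = 0.05, df = NULL) {
  lambda <- sqrt(ns / (ns + n_control))
  df <- df %||% (sum(ns) + n_control - length(ns) - 1L)
  uniroot(function(q) pdunnett_abs(q, lambda, df) - (1 - alpha),
          lower = 1e-3, upper = 15, tol = 1e-8)$root
}

#' Dunnett's many-to-one comparisons against a control
#'
#' Two-sided comparisons of every treatment group mean against the control
#' group mean with pooled variance and single-step Dunnett adjustment
#' (equicorrelated multivariate t; unbalanced allocation supported through
#' the group-size correlations). With a single treatment group the adjusted
#' p-value equals the pooled-variance two-sided t-test.
#'
#' @param groups Named list of numeric vectors (one per group, including the
#'   control), each of length >= 2.
#' @param control Name of the control group.
#' @param alpha Significance level used for the `significant` column.
#' @return A data frame with one row per treatment group: `group`, `n`,
#'   `mean`, `diff` (vs control), `t`, `p_adj`, `significant`; attributes
#'   `df`, `control`, `pooled_sd`.
#' @examples
#' g <- list(control = rnorm(10), a = rnorm(10, 1), b = rnorm(10))
#' dunnett_vs_control(g, "control")
#' @export
dunnett_vs_control <- function(groups, control, alpha = 0.05) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    stop("`groups` must be a named list of numeric vectors", call. = FALSE)
  }
  if (!control %in% names(groups)) {
    stop(sprintf("control label '%s' not found among groups (%s)", control,
                 paste(names(groups), collapse = ", ")), call. = FALSE)
  }
  ns <- vapply(groups, length, 0L)
  if (any(ns < 2L)) stop("every group needs n >= 2", call. = FALSE)
  if (length(groups) < 2L) stop("need at least one treatment group", call. = FALSE)
  k <- length(groups)
  df <- sum(ns) - k
  means <- vapply(groups, mean, 0)
  s2 <- sum(vapply(groups, function(g) (length(g) - 1) * var(g), 0)) / df
  trt <- setdiff(names(groups), control)
  n0 <- ns[[control]]
  lambda <- sqrt(ns[trt] / (ns[trt] + n0))
  tval <- (means[trt] - means[[control]]) / sqrt(s2 * (1 / ns[trt] + 1 / n0))
  p_adj <- vapply(abs(tval), function(q) 1 - pdunnett_abs(q, lambda, df), 0)
  out <- data.frame(group = trt, n = as.integer(ns[trt]), mean = means[trt],
                    diff = means[trt] - means[[control]], t = tval,
                    p_adj = p_adj, significant = p_adj < alpha,
                    row.names = NULL)
  attr(out, "df") <- df
  attr(out, "control") <- control
  attr(out, "pooled_sd") <- sqrt(s2)
  out
}

# --- BCa bootstrap ----------------------------------------------------------

#' BCa bootstrap confidence interval for a difference of means
#'
#' Statistic: `mean(group) - mean(control)`. Each arm is resampled
#' independently with replacement. The bias-correction z0 comes from the
#' fraction of bootstrap statistics below the observed value; the
#' acceleration comes from the pooled per-arm jackknife (leave one
#' observation out of either arm) skewness. Endpoints are the BCa-adjusted
#' percentiles of the bootstrap distribution.
#'
#' @param group,control Numeric samples, each n >= 2.
#' @param n_boot Bootstrap replications (default `1e5`).
#' @param level Confidence level.
#' @param seed Integer seed; fixed seed gives bit-identical intervals.
#' @return An object of class `effect_estimate`: list with `mean_difference`,
#'   `ci_low`, `ci_high`, `level`, `n_boot`, `group_n`, `control_n`, `z0`,
#'   `acceleration`, `degenerate`.
#' @examples
#' est <- bootstrap_bca_diff(rnorm(20, 1), rnorm(20), n_boot = 2000, seed = 1)
#' est$mean_difference
#' @export
bootstrap_bca_diff <- function(group, control, n_boot = 1e5, level = 0.95,
                               seed = NULL) {
  ng <- length(group); nc <- length(control)
  if (ng < 2L || nc < 2L) stop("both samples need n >= 2", call. = FALSE)
  check_number(n_boot, "n_boot", 2, integer = TRUE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  obs <- mean(group) - mean(control)

  boot_stats <- with_seed(seed, {
    bg <- .colMeans(sample(group, ng * n_boot, replace = TRUE), ng, n_boot)
    bc <- .colMeans(sample(control, nc * n_boot, replace = TRUE), nc, n_boot)
    bg - bc
  })

  make <- function(lo, hi, z0 = NA_real_, a = NA_real_, degenerate = FALSE) {
    structure(list(mean_difference = obs, ci_low = lo, ci_high = hi,
                   level = level, n_boot = as.integer(n_boot),
                   group_n = ng, control_n = nc, z0 = z0, acceleration = a,
                   degenerate = degenerate),
              class = "effect_estimate")
  }
  if (diff(range(boot_stats)) == 0) {
    return(make(obs, obs, degenerate = TRUE))
  }
  prop <- mean(boot_stats < obs)
  prop <- min(max(prop, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
  z0 <- qnorm(prop)
  # pooled per-arm jackknife
  jack <- c((sum(group) - group) / (ng - 1) - mean(control),
            mean(group) - (sum(control) - control) / (nc - 1))
  dev <- mean(jack) - jack
  denom <- sum(dev^2)^1.5
  a <- if (denom == 0) 0 else sum(dev^3) / (6 * denom)
  zlo <- qnorm((1 - level) / 2)
  zhi <- -zlo
  adj <- function(zq) pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  probs <- c(adj(zlo), adj(zhi))
  ci <- quantile(boot_stats, probs, names = FALSE, type = 7)
  make(ci[1L], ci[2L], z0 = z0, a = a)
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Mean difference: %.4g  [%.4g, %.4g] (%g%% BCa, %d replications)\n",
              x$mean_difference, x$ci_low, x$ci_high, 100 * x$level, x$n_boot))
  if (x$degenerate) cat("  (degenerate: all bootstrap statistics identical)\n")
  invisible(x)
}

# --- screen matrix and clustering -------------------------------------------

#' Build the screen ratio matrix with Z-scores
#'
#' Per-cell ratios `F_post / F_pre` are averaged into a Rab x construct
#' matrix; Z-scores are computed per column (one column = one construct's
#' screen), per row, or globally.
#'
#' @param measurements Data frame with columns `construct`, `rab`, `F_pre`,
#'   `F_post` (e.g. from [simulate_screen()]).
#' @param standardize `"column"` (default), `"row"`, or `"global"`.
#' @return An object of class `screen_matrix`: list with `values`, `zscores`
#'   (same shape), and `standardize`.
#' @export
build_screen_matrix <- function(measurements,
                                standardize = c("column", "row", "global")) {
  standardize <- match.arg(standardize)
  req <- c("construct", "rab", "F_pre", "F_post")
  if (!all(req %in% names(measurements))) {
    stop("`measurements` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(measurements$F_pre <= 0)) stop("F_pre must be > 0", call. = FALSE)
  ratio <- measurements$F_post / measurements$F_pre
  values <- tapply(ratio, list(measurements$rab, measurements$construct), mean)
  if (anyNA(values)) {
    missing <- which(is.na(values), arr.ind = TRUE)
    stop("missing (rab, construct) combinations: ",
         paste(sprintf("(%s, %s)", rownames(values)[missing[, 1L]],
                       colnames(values)[missing[, 2L]]), collapse = ", "),
         call. = FALSE)
  }
  values <- values[, , drop = FALSE]
  z <- switch(standardize,
    column = {
      sds <- apply(values, 2L, sd)
      if (any(!is.finite(sds)) || any(sds == 0)) {
        stop("constant column; Z-score undefined — use standardize = \"global\"",
             call. = FALSE)
      }
      scale(values)
    },
    row = {
      sds <- apply(values, 1L, sd)
      if (any(!is.finite(sds)) || any(sds == 0)) {
        stop("constant row; Z-score undefined — use standardize = \"global\"",
             call. = FALSE)
      }
      t(scale(t(values)))
    },
    global = {
      s <- sd(values)
      if (!is.finite(s) || s == 0) stop("constant matrix; Z-score undefined", call. = FALSE)
      (values - mean(values)) / s
    })
  z <- z[, , drop = FALSE]
  attributes(z)[c("scaled:center", "scaled:scale")] <- NULL
  dimnames(z) <- dimnames(values)
  structure(list(values = values, zscores = z, standardize = standardize),
            class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("<screen_matrix> %d rabs x %d constructs (%s Z-scores)\n",
              nrow(x$values), ncol(x$values), x$standardize))
  print(round(x$values, 3))
  invisible(x)
}

#' Hierarchically cluster Rab profiles
#'
#' Agglomerative clustering of matrix rows (Rabs) on Euclidean distances of
#' the Z-scored profiles. Leaf order is deterministic (ties broken by lower
#' original row index, the `hclust` convention).
#'
#' @param x A `screen_matrix` (or a plain numeric matrix).
#' @param linkage `"complete"` (default), `"average"`, or `"ward"`.
#' @param k Optional number of flat clusters to cut.
#' @param use Cluster on `"zscores"` (default) or raw `"values"` (ignored for
#'   plain matrices).
#' @return A list with `hclust`, `order` (leaf labels in dendrogram order),
#'   and `clusters` (named integer vector, or `NULL` if `k` is missing).
#' @export
cluster_screen <- function(x, linkage = c("complete", "average", "ward"),
                           k = NULL, use = c("zscores", "values")) {
  linkage <- match.arg(linkage)
  use <- match.arg(use)
  m <- if (inherits(x, "screen_matrix")) x[[use]] else as.matrix(x)
  if (nrow(m) < 2L) stop("need >= 2 rows to cluster", call. = FALSE)
  if (anyNA(m) || any(!is.finite(m))) stop("matrix contains NA/Inf", call. = FALSE)
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- hclust(dist(m), method = method)
  clusters <- if (!is.null(k)) cutree(hc, k = k)
  list(hclust = hc, order = rownames(m)[hc$order], clusters = clusters)
}

#' Classify Rabs into INV populations by screen membership
#'
#' Assigns each hit Rab to the subset of constructs in which it scored
#' significant (Dunnett adjusted p below `alpha` against the fluorophore
#' control), i.e. its Euler-set membership class. Rabs significant nowhere
#' are excluded.
#'
#' @param hits Data frame with columns `construct`, `rab`, and either
#'   `p_adj` or logical `significant`.
#' @param alpha Threshold applied to `p_adj` when `significant` is absent.
#' @return Data frame with one row per hit Rab: `rab`, `class` (construct
#'   labels joined with `+`), `n_constructs`.
#' @export
classify_inv_populations <- function(hits, alpha = 0.05) {
  if (!all(c("construct", "rab") %in% names(hits))) {
    stop("`hits` needs columns construct and rab", call. = FALSE)
  }
  sig <- if ("significant" %in% names(hits)) as.logical(hits$significant)
         else if ("p_adj" %in% names(hits)) hits$p_adj < alpha
         else stop("`hits` needs a p_adj or significant column", call. = FALSE)
  hit <- hits[sig, , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(rab = character(0), class = character(0),
                      n_constructs = integer(0)))
  }
  cls <- vapply(split(as.character(hit$construct), as.character(hit$rab)),
                function(cs) paste(sort(unique(cs)), collapse = "+"), "")
  data.frame(rab = names(cls), class = unname(cls),
             n_constructs = lengths(strsplit(unname(cls), "+", fixed = TRUE)),
             row.names = NULL)
}
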