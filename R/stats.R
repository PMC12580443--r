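#' Exact binomial prevalence test with Clopper-Pearson interval
#'
#' Tests an observed prevalence `k / n` against `p0`. The default two-sided
#' p-value doubles the smaller tail, `min(1, 2 * min(P(X <= k), P(X >= k)))`
#' under Binomial(n, p0); `method = "minlik"` instead sums all outcomes no
#' more likely than the observed one (the [stats::binom.test()] rule). The
#' 95% Clopper-Pearson bounds are the inverse-incomplete-beta closed form:
#' lower `qbeta(alpha/2; k, n-k+1)` (0 when k = 0), upper
#' `qbeta(1-alpha/2; k+1, n-k)` (1 when k = n).
#'
#' @param k successes (subjects with segmentation).
#' @param n trials (subjects).
#' @param p0 null proportion.
#' @param alpha 1 - confidence level.
#' @param method `"doubled"` tail-doubling (default) or `"minlik"`.
#' @return object of class `prevalence_result`: list with `k`, `n`, `phat`,
#'   `p_two_sided`, `ci_low`, `ci_high`, `p0`, `conf_level`.
#' @export
prevalence_test <- function(k, n, p0 = 0.5, alpha = 0.05,
                            method = c("doubled", "minlik")) {
  method <- match.arg(method)
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("need integer 0 <= k <= n, n >= 1")
  }
  if (method == "doubled") {
    lower <- stats::pbinom(k, n, p0)
    upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
  } else {
    p <- stats::binom.test(k, n, p0)$p.value
  }
  ci_low <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  ci_high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(list(k = k, n = n, phat = k / n, p_two_sided = p,
                 ci_low = ci_low, ci_high = ci_high,
                 p0 = p0, conf_level = 1 - alpha, method = method),
            class = "prevalence_result")
}

#' @export
print.prevalence_result <- function(x, ...) {
  cat(sprintf("Exact binomial test: %d / %d = %.0f%% (null %.0f%%)\n",
              x$k, x$n, 100 * x$phat, 100 * x$p0))
  cat(sprintf("  p = %.4g (two-sided, %s), %.0f%% Clopper-Pearson CI [%.2f, %.2f]\n",
              x$p_two_sided, x$method, 100 * x$conf_level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Kruskal-Wallis omnibus test
#'
#' Thin wrapper over [stats::kruskal.test()] (midrank ties, tie-corrected H,
#' chi-square reference with `length(groups) - 1` df) with the degenerate
#' all-identical case fixed at `H = 0, p = 1`.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return list with `H`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(!vapply(groups, length, 1L))) {
    stop("need >= 2 nonempty groups")
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1, n = length(x)))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = length(x))
}

# tie term sum(t^3 - t) over pooled tie groups
tie_term <- function(x) {
  tt <- table(x)
  sum(tt^3 - tt)
}

#' Dunn's pairwise comparisons after Kruskal-Wallis
#'
#' Dunn's z on pooled midranks with tie correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over pooled tie groups. Two-sided p-values are
#' Bonferroni-adjusted with m = g(g-1)/2 contrasts (one family per
#' measure), and each contrast carries the effect size
#' `r = |z| / sqrt(n_i + n_j)`.
#'
#' @param groups list of numeric vectors.
#' @param labels group names (defaults to list names or G1..Gk).
#' @return data.frame with columns `group1`, `group2`, `z`, `p_unadj`,
#'   `p_adj`, `r`, `n_pair`.
#' @export
dunn_pairwise_bonferroni <- function(groups, labels = NULL) {
  gk <- length(groups)
  if (gk < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group in pairwise comparison")
  if (is.null(labels)) {
    labels <- if (!is.null(names(groups))) names(groups) else paste0("G", seq_len(gk))
  }
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  rk <- rank(x)
  sizes <- vapply(groups, length, 1L)
  gid <- rep(seq_len(gk), sizes)
  rbar <- tapply(rk, gid, mean)
  sig2 <- N * (N + 1) / 12 - tie_term(x) / (12 * (N - 1))
  m <- gk * (gk - 1) / 2
  out <- list()
  for (i in seq_len(gk - 1L)) {
    for (j in (i + 1L):gk) {
      se <- sqrt(sig2 * (1 / sizes[i] + 1 / sizes[j]))
      z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
      p <- 2 * stats::pnorm(-abs(z))
      np <- sizes[i] + sizes[j]
      out[[length(out) + 1L]] <- data.frame(
        group1 = labels[i], group2 = labels[j], z = z,
        p_unadj = p, p_adj = min(1, p * m),
        r = effect_size_r(z, np), n_pair = np,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert a pairwise z score to the effect size r
#'
#' `r = |z| / sqrt(n_pair)` with `n_pair` the summed size of the two
#' compared groups; 0.10 / 0.30 / 0.50 are the conventional small /
#' moderate / large benchmarks.
#'
#' @param z standardized test statistic.
#' @param n_pair total observations in the two groups.
#' @return r in `[0, Inf)` (in practice `[0, 1]`).
#' @export
effect_size_r <- function(z, n_pair) {
  if (any(n_pair < 2)) stop("n_pair must be >= 2")
  abs(z) / sqrt(n_pair)
}

#' Mann-Whitney U test with tie-corrected z and small-sample exact p
#'
#' Computes `U` for the first group from pooled midranks, the
#' normal-approximation z with tie correction, its two-sided p, and the
#' effect size `r = |z| / sqrt(n1 + n2)`. When `n1 + n2 <= exact_max`
#' (default 12) an exact two-sided p is also reported, computed by
#' enumerating all `choose(N, n1)` group labelings of the pooled values and
#' counting labelings with `|U - n1 n2 / 2|` at least as extreme.
#'
#' @param g1,g2 numeric vectors.
#' @param exact_max largest `n1 + n2` for which the exact p is enumerated.
#' @return list with `U`, `z`, `p`, `r`, `n1`, `n2`, and `p_exact`
#'   (NA when not enumerated).
#' @export
mann_whitney <- function(g1, g2, exact_max = 12L) {
  n1 <- length(g1); n2 <- length(g2)
  if (!n1 || !n2) stop("both groups must be nonempty")
  x <- c(g1, g2)
  N <- n1 + n2
  rk <- rank(x)
  R1 <- sum(rk[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term(x) / (N * (N - 1)))
  z <- if (sig2 > 0) (U - mu) / sqrt(sig2) else 0
  p <- if (sig2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  p_exact <- NA_real_
  if (N <= exact_max) {
    combos <- utils::combn(N, n1)
    obs <- abs(U - mu)
    us <- apply(combos, 2L, function(ii) sum(rk[ii]) - n1 * (n1 + 1) / 2)
    p_exact <- mean(abs(us - mu) >= obs - 1e-12)
  }
  list(U = U, z = z, p = p, p_exact = p_exact,
       r = effect_size_r(z, N), n1 = n1, n2 = n2)
}

# tie-corrected Friedman chi-square on a complete-case matrix
friedman_chi2 <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  rk <- t(apply(mat, 1L, rank))
  if (k == 1L) stop("need >= 2 conditions")
  Rj <- colSums(rk)
  A <- sum(rk^2)
  C <- n * k * (k + 1)^2 / 4
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  if (A == C) return(list(chi2 = 0, df = k - 1L, p = 1))
  chi2 <- num / (A - C)
  list(chi2 = chi2, df = k - 1L, p = stats::pchisq(chi2, k - 1L, lower.tail = FALSE))
}

#' Friedman test with stepwise step-down homogeneous subsets
#'
#' Tie-corrected Friedman chi-square (within-row midranks; Conover's
#' `(k-1) * sum((R_j - n(k+1)/2)^2) / (sum r_ij^2 - nk(k+1)^2/4)` form,
#' which reduces to the classical statistic without ties) on a
#' subjects-by-conditions matrix; rows with missing values are dropped and
#' the count reported. Homogeneous subsets are grown step-down: order
#' conditions by mean rank, grow a subset from the lowest-ranked condition
#' while the Friedman test restricted to the candidate subset has
#' `p > alpha`, close the subset, and restart from the first excluded
#' condition; subsets may overlap.
#'
#' @param mat numeric matrix or data.frame, rows = subjects, columns =
#'   conditions (e.g. ordinal slowing periods).
#' @param alpha subset homogeneity level.
#' @return object of class `friedman_result`: list with `chi2`, `df`, `p`,
#'   `n_used`, `n_dropped`, `mean_ranks`, `homogeneous_subsets` (list of
#'   condition-name vectors).
#' @export
friedman_stepdown <- function(mat, alpha = 0.05) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("C", seq_len(ncol(mat)))
  cc <- stats::complete.cases(mat)
  dropped <- sum(!cc)
  mat <- mat[cc, , drop = FALSE]
  if (ncol(mat) < 2L) stop("need >= 2 conditions")
  if (nrow(mat) < 2L) stop("need >= 2 complete rows")
  main <- friedman_chi2(mat)
  rk <- t(apply(mat, 1L, rank))
  mean_ranks <- colMeans(rk)
  ord <- order(mean_ranks)
  k <- ncol(mat)
  # maximal homogeneous runs in mean-rank order; runs contained in an
  # earlier run are discarded, so subsets may overlap (e.g. conditions 2-4
  # and 3-5) without duplicating nested ones
  runs <- list()
  for (start in seq_len(k)) {
    end <- start
    while (end < k) {
      cand <- ord[start:(end + 1L)]
      pv <- friedman_chi2(mat[, cand, drop = FALSE])$p
      if (pv > alpha) end <- end + 1L else break
    }
    runs[[start]] <- c(start, end)
  }
  subsets <- list()
  prev_end <- 0L
  for (r in runs) {
    if (r[2L] > prev_end) {
      subsets[[length(subsets) + 1L]] <- colnames(mat)[ord[r[1L]:r[2L]]]
      prev_end <- r[2L]
    }
  }
  structure(list(chi2 = main$chi2, df = main$df, p = main$p,
                 n_used = nrow(mat), n_dropped = dropped,
                 mean_ranks = mean_ranks,
                 homogeneous_subsets = subsets),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi2(%d) = %.3f, p = %.4g (n = %d complete rows, %d dropped)\n",
              x$df, x$chi2, x$p, x$n_used, x$n_dropped))
  for (s in x$homogeneous_subsets) {
    cat("  homogeneous subset: ", paste(s, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Median, IQR and coefficient of variation
#'
#' Quantiles use the linear-interpolation convention ([stats::quantile()]
#' type 7); IQR = Q3 - Q1; CV = 100 * sd / mean with the n-1 denominator.
#' CV is `NA` (with a warning) when the mean is 0 or fewer than 2 values
#' are supplied.
#'
#' @param values numeric vector.
#' @return list with `median`, `iqr`, `cv_percent`, `n`.
#' @export
descriptives <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  med <- stats::median(values)
  iqr <- unname(stats::quantile(values, 0.75, type = 7) -
                stats::quantile(values, 0.25, type = 7))
  cv <- NA_real_
  if (length(values) >= 2L) {
    mu <- mean(values)
    if (mu == 0) warning("mean is 0: CV undefined") else cv <- 100 * stats::sd(values) / mu
  }
  list(median = med, iqr = iqr, cv_percent = cv, n = length(values))
}

#' Cohort-level inference report
#'
#' Assembles the full inference layer from a subject-summary table (see
#' [summarize_cohort()]): segmentation prevalence among PD subjects (exact
#' binomial vs. 50% with Clopper-Pearson CI), a Kruskal-Wallis omnibus plus
#' Dunn/Bonferroni pairwise block (with r effect sizes) per force measure
#' across PD_Seg / PD_NoSeg / OA, Friedman tests with step-down homogeneous
#' subsets over the ordinal segment and slowing-period duration medians in
#' PD_Seg, and per-ordinal descriptives (median, IQR, CV across PD_Seg
#' subjects).
#'
#' @param summaries subject-summary data.frame.
#' @param measures character vector of summary columns to compare across
#'   groups.
#' @param alpha significance level for subsets.
#' @return object of class `cohort_report`.
#' @export
cohort_stats_report <- function(summaries,
                                measures = c("med_n_seg_f90", "med_n_seg_peak",
                                             "med_rfd_pk", "med_t_f90",
                                             "med_t_pf", "med_first_seg_dur",
                                             "med_t_rfd_pk", "med_rfd_pk_seg1",
                                             "med_seg_of_rfd_pk"),
                                alpha = 0.05) {
  need <- c("subject_id", "group_final")
  if (!all(need %in% names(summaries))) {
    stop("subject summaries missing columns: ",
         paste(setdiff(need, names(summaries)), collapse = ", "))
  }
  grp <- summaries$group_final
  n_pd <- sum(grp %in% c("PD_Seg", "PD_NoSeg"))
  k_seg <- sum(grp == "PD_Seg")
  prevalence <- if (n_pd >= 1) prevalence_test(k_seg, n_pd) else NULL
  glevels <- c("PD_Seg", "PD_NoSeg", "OA")
  present <- glevels[glevels %in% grp]
  tests <- list()
  if (length(present) >= 2L) {
    for (mm in measures) {
      if (!mm %in% names(summaries)) next
      gl <- lapply(present, function(g) {
        v <- summaries[[mm]][grp == g]
        v[is.finite(v)]
      })
      names(gl) <- present
      if (any(vapply(gl, length, 1L) == 0L)) next
      om <- kruskal_wallis(gl)
      pw <- dunn_pairwise_bonferroni(gl, labels = present)
      tests[[mm]] <- list(omnibus = om, pairwise = pw)
    }
  } else {
    warning("fewer than 2 groups present: omnibus blocks skipped")
  }
  durations <- list()
  seg_cols <- paste0("med_seg_dur", 1:5)
  slow_cols <- paste0("med_slow_dur", 1:5)
  seg_subj <- summaries[grp == "PD_Seg", , drop = FALSE]
  for (fam in list(list(name = "segment_durations", cols = seg_cols),
                   list(name = "slowing_durations", cols = slow_cols))) {
    cols <- fam$cols[fam$cols %in% names(seg_subj)]
    if (length(cols) >= 2L && nrow(seg_subj) >= 2L) {
      mat <- as.matrix(seg_subj[, cols])
      desc <- lapply(cols, function(cc) {
        v <- seg_subj[[cc]]
        v <- v[is.finite(v)]
        if (length(v)) descriptives(v) else NULL
      })
      names(desc) <- cols
      fr <- tryCatch(friedman_stepdown(mat, alpha = alpha),
                     error = function(e) NULL)
      durations[[fam$name]] <- list(friedman = fr, descriptives = desc)
    }
  }
  structure(list(prevalence = prevalence, tests = tests,
                 durations = durations, groups = table(grp),
                 alpha = alpha),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort segmentation report\n")
  cat("  groups: ", paste(names(x$groups), x$groups, sep = "=", collapse = ", "), "\n", sep = "")
  if (!is.null(x$prevalence)) {
    cat(sprintf("  prevalence of segmentation among PD: %d/%d = %.0f%%, p = %.3f, CI [%.2f, %.2f]\n",
                x$prevalence$k, x$prevalence$n, 100 * x$prevalence$phat,
                x$prevalence$p_two_sided, x$prevalence$ci_low, x$prevalence$ci_high))
  }
  for (mm in names(x$tests)) {
    om <- x$tests[[mm]]$omnibus
    cat(sprintf("  %s: H(%d) = %.1f, p = %.4g\n", mm, om$df, om$H, om$p))
    pw <- x$tests[[mm]]$pairwise
    for (i in seq_len(nrow(pw))) {
      cat(sprintf("    %s vs %s: z = %.2f, p_adj = %.3g, r = %.2f\n",
                  pw$group1[i], pw$group2[i], pw$z[i], pw$p_adj[i], pw$r[i]))
    }
  }
  for (fam in names(x$durations)) {
    fr <- x$durations[[fam]]$friedman
    if (!is.null(fr)) {
      cat(sprintf("  %s: chi2(%d) = %.2f, p = %.4g\n", fam, fr$df, fr$chi2, fr$p))
    }
  }
  invisible(x)
}

#' Serialize a cohort report to JSON
#'
#' @param report a `cohort_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  pl <- report$prevalence
  obj <- list(
    groups = as.list(report$groups),
    prevalence = if (!is.null(pl)) {
      list(k = pl$k, n = pl$n, phat = pl$phat, p_two_sided = pl$p_two_sided,
           ci_low = pl$ci_low, ci_high = pl$ci_high)
    },
    measures = lapply(report$tests, function(tt) {
      list(omnibus = tt$omnibus, pairwise = tt$pairwise)
    }),
    durations = lapply(report$durations, function(dd) {
      list(friedman = if (!is.null(dd$friedman)) {
        list(chi2 = dd$friedman$chi2, df = dd$friedman$df, p = dd$friedman$p,
             n_used = dd$friedman$n_used,
             homogeneous_subsets = dd$friedman$homogeneous_subsets)
      },
      descriptives = dd$descriptives)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
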