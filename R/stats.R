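#' Wilcoxon signed-rank test for paired bare/shod measures
#'
#' Classical paired signed-rank test: zero differences are dropped
#' (Wilcoxon's convention), ties receive average ranks, and the
#' two-sided p-value uses the exact null distribution for
#' `n_effective <= 25` without ties and the normal approximation with
#' continuity correction otherwise. The median of the differences is
#' reported alongside.
#'
#' @param x,y paired numeric vectors (e.g. bare and shod); the test is
#'   on `y - x`. Alternatively pass precomputed differences as `x` with
#'   `y = NULL`.
#' @return list with `statistic` (V, sum of positive ranks), `p.value`,
#'   `n_effective`, `median_diff`, `method`, `defined` (FALSE when all
#'   differences are zero).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(y) - as.numeric(x)
  if (length(d) < 1L) stop("need at least one pair")
  med <- median(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; statistic undefined")
    return(list(statistic = NA_real_, p.value = 1.0, n_effective = 0L,
                median_diff = med, method = "degenerate", defined = FALSE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (!ties && n <= 25L) {
    # exact two-sided tail via the symmetric signed-rank null
    p <- min(1, 2 * min(psignrank(V, n), 1 - psignrank(V - 1, n)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24
    tie_tab <- table(r)
    sig2 <- sig2 - sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sig2)  # continuity correction
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = V, p.value = p, n_effective = n, median_diff = med,
       method = method, defined = TRUE)
}

#' Paired bare-vs-shod comparison over all entities of a metric
#'
#' Pairs bare and shod values of one metric by (configuration, entity,
#' frame bone), runs [wilcoxon_signed_rank()] per entity, and reports
#' the fraction of entities significant at `alpha`. Entities without
#' overlapping pairs are flagged, not dropped.
#'
#' @param measures long table as produced by [measure_all()]; pairing
#'   requires matching `config_id` apart from the footwear label.
#' @param metric_type one of `"translation_mm"`, `"rotation_deg"`,
#'   `"angle_deg"`, `"strain_pct"`.
#' @param alpha significance level, default 0.05. No multiple-testing
#'   correction is applied; p-values are raw.
#' @param by_foot optional column name to additionally group by (e.g.
#'   a foot id), testing per group instead of pooling.
#' @return data.frame: `entity`, `frame_bone`, `n`, `statistic`, `p`,
#'   `median_diff`, `significant`, with attribute
#'   `"significant_fraction"`.
#' @export
paired_comparison_table <- function(measures, metric_type, alpha = 0.05,
                                    by_foot = NULL) {
  m <- measures[measures$metric_type == metric_type, , drop = FALSE]
  if (nrow(m) == 0L) stop("no rows with metric_type ", metric_type)
  if (!all(c("bare", "shod") %in% m$footwear))
    stop("measures must contain both footwear levels")
  # pair key: configuration id with the footwear token removed
  m$pair_key <- paste(m$orientation, m$load_bw,
                      if (!is.null(by_foot)) m[[by_foot]] else "")
  groups <- split(m, list(m$entity, m$frame_bone), drop = TRUE)
  rows <- lapply(groups, function(g) {
    bare <- g[g$footwear == "bare", ]
    shod <- g[g$footwear == "shod", ]
    key <- intersect(bare$pair_key, shod$pair_key)
    ent <- g$entity[1]; fb <- g$frame_bone[1]
    if (length(key) == 0L)
      return(data.frame(entity = ent, frame_bone = fb, n = 0L,
                        statistic = NA_real_, p = NA_real_,
                        median_diff = NA_real_, significant = NA))
    b <- bare$value[match(key, bare$pair_key)]
    s <- shod$value[match(key, shod$pair_key)]
    w <- suppressWarnings(wilcoxon_signed_rank(b, s))
    data.frame(entity = ent, frame_bone = fb, n = w$n_effective,
               statistic = w$statistic, p = w$p.value,
               median_diff = w$median_diff,
               significant = is.finite(w$p.value) && w$p.value < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !is.na(out$significant)
  attr(out, "significant_fraction") <- mean(out$significant[ok])
  out
}
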