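# Empirical quantile as an attained order statistic (no interpolation):
# the ceiling-index value, so funnel limits are values actually observed
# among the replicates.
attained_quantile <- function(x, p) {
  xs <- sort(x)
  xs[pmin(length(xs), pmax(1L, ceiling(p * length(xs))))]
}

# Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Draw a random subsample of OTUs from a master list
#'
#' Samples `s` distinct OTUs uniformly without replacement, with no
#' stratification by higher taxa.
#'
#' @param master a `taxonomy`.
#' @param s subsample dimension, `2 <= s <= S`.
#' @param seed optional integer seed (the caller's RNG stream is restored).
#' @return character vector of `s` OTU names.
#' @export
random_subsample <- function(master, s, seed = NULL) {
  otus <- otu_names(master)
  s <- as.integer(s)
  if (s < 2L || s > length(otus)) {
    stop("'s' must be between 2 and the master dimension ", length(otus))
  }
  with_seed(seed, sample(otus, s))
}

#' Replicate AvTD/VarTD values from random subsamples
#'
#' Draws `k` random subsamples of dimension `s` from the master list and
#' computes AvTD and VarTD of each under master-derived step lengths.  This
#' is the null distribution a real sample of the same dimension is judged
#' against.
#'
#' @param master a `taxonomy`.
#' @param s subsample dimension.
#' @param k number of replicates (100 or 1,000 are reasonable defaults; very
#'   large `k` converges on the absolute extremes).
#' @param scheme a `step_lengths` object or kind string (resolved against
#'   the master).
#' @param seed optional integer seed.
#' @return an object of class `"replicate_set"`: list with `s`, `k`,
#'   `avtd_values`, `vartd_values`, `scheme_kind`, `seed`.
#' @export
replicate_set <- function(master, s, k = 100, scheme = "proportional",
                          seed = NULL) {
  scheme <- resolve_scheme(scheme, master)
  d <- taxonomic_distance(master, scheme)
  with_seed(seed, {
    out <- replicate_stats(d, s, k)
    structure(list(s = as.integer(s), k = as.integer(k),
                   avtd_values = out$avtd, vartd_values = out$vartd,
                   scheme_kind = scheme$kind, seed = seed),
              class = "replicate_set")
  })
}

# k replicates of (avtd, vartd) at dimension s from a precomputed master
# distance matrix: a pruned sample tree measured with master step lengths
# has exactly the master's pairwise distances restricted to the sample.
replicate_stats <- function(d, s, k) {
  n <- nrow(d)
  if (s < 2L || s > n) stop("'s' must be between 2 and ", n)
  a <- numeric(k)
  v <- numeric(k)
  ut <- upper.tri(matrix(0, s, s))
  for (r in seq_len(k)) {
    idx <- sample.int(n, s)
    w <- d[idx, idx][ut]
    a[r] <- mean(w)
    v[r] <- mean((w - a[r])^2)
  }
  list(avtd = a, vartd = v)
}

#' Funnel analysis of a master taxonomy
#'
#' For each subsample dimension `s` in `s_range`, draws `k` random
#' subsamples from the master list, computes AvTD and VarTD of each under
#' master step lengths, and summarizes the replicate distributions with the
#' lines of a funnel plot: the mean, the one-tailed 95% limit (5th
#' percentile for AvTD, 95th for VarTD — low distinctness and high variation
#' being the unwanted directions), and the observed extreme (maximum AvTD,
#' minimum VarTD).  A real sample is judged by where its dot falls relative
#' to these lines at its own dimension.
#'
#' @param master a `taxonomy`.
#' @param s_range integer vector of subsample dimensions.
#' @param k replicates per dimension.
#' @param scheme a `step_lengths` object or kind string.
#' @param seed optional integer seed; with a fixed seed the whole table is
#'   reproducible.
#' @param conf one-tailed confidence level (default 0.95).
#' @return a data frame of class `"funnel_table"` with columns `s`,
#'   `mean_avtd`, `lower95_avtd`, `max_avtd`, `mean_vartd`, `upper95_vartd`,
#'   `min_vartd`; attributes `k`, `seed`, `scheme_kind`, `master_avtd`,
#'   `master_vartd`.
#' @examples
#' m <- synthetic_taxonomy(c(60, 20, 6, 1), seed = 1)
#' funnel_analysis(m, s_range = c(5, 10, 20), k = 50, seed = 1)
#' @export
funnel_analysis <- function(master, s_range, k = 100,
                            scheme = "proportional", seed = NULL,
                            conf = 0.95) {
  scheme <- resolve_scheme(scheme, master)
  s_range <- sort(unique(as.integer(s_range)))
  d <- taxonomic_distance(master, scheme)
  if (any(s_range < 2L) || any(s_range > nrow(d))) {
    stop("subsample dimensions must lie between 2 and the master dimension ",
         nrow(d))
  }
  rows <- with_seed(seed, lapply(s_range, function(s) {
    st <- replicate_stats(d, s, k)
    data.frame(s = s,
               mean_avtd = mean(st$avtd),
               lower95_avtd = attained_quantile(st$avtd, 1 - conf),
               max_avtd = max(st$avtd),
               mean_vartd = mean(st$vartd),
               upper95_vartd = attained_quantile(st$vartd, conf),
               min_vartd = min(st$vartd))
  }))
  out <- do.call(rbind, rows)
  mv <- d[upper.tri(d)]
  structure(out, class = c("funnel_table", "data.frame"),
            k = as.integer(k), seed = seed, scheme_kind = scheme$kind,
            conf = conf,
            master_avtd = mean(mv),
            master_vartd = mean((mv - mean(mv))^2))
}

#' Randomization test of a sample against its master list
#'
#' One-tailed by default: representativeness asks whether the sample's AvTD
#' is unusually *low* (and its VarTD unusually *high*) compared with random
#' subsamples of the same dimension — a sample more distinct than random is
#' welcome, not suspect.  The p-values are
#' `p_avtd  = (1 + #\{replicate AvTD <= observed\}) / (k + 1)` and
#' `p_vartd = (1 + #\{replicate VarTD >= observed\}) / (k + 1)`.
#' `tail = "two"` doubles the smaller tail (capped at 1), reproducing the
#' original ecological two-tailed test that flags both unusually poor and
#' unusually rich assemblages.
#'
#' @param observed a `"distinctness"` object (see [distinctness()]), or a
#'   list with elements `s`, `avtd`, `vartd`.
#' @param replicates a `"replicate_set"` of the same dimension `s`.
#' @param tail `"one"` (default) or `"two"`.
#' @return a list with `p_avtd`, `p_vartd`, `tail`, `s`, `k`.
#' @export
significance_test <- function(observed, replicates, tail = c("one", "two")) {
  tail <- match.arg(tail)
  stopifnot(inherits(replicates, "replicate_set"))
  if (observed$s != replicates$s) {
    stop("observed sample dimension (", observed$s,
         ") does not match replicate dimension (", replicates$s, ")")
  }
  k <- replicates$k
  p_lo_a <- (1 + sum(replicates$avtd_values <= observed$avtd)) / (k + 1)
  p_hi_a <- (1 + sum(replicates$avtd_values >= observed$avtd)) / (k + 1)
  p_lo_v <- (1 + sum(replicates$vartd_values <= observed$vartd)) / (k + 1)
  p_hi_v <- (1 + sum(replicates$vartd_values >= observed$vartd)) / (k + 1)
  if (tail == "one") {
    list(p_avtd = p_lo_a, p_vartd = p_hi_v, tail = tail,
         s = observed$s, k = k)
  } else {
    list(p_avtd = min(1, 2 * min(p_lo_a, p_hi_a)),
         p_vartd = min(1, 2 * min(p_lo_v, p_hi_v)),
         tail = tail, s = observed$s, k = k)
  }
}

#' Moment and quantile summary of a replicate distribution
#'
#' Diagnostic description of the replicate AvTD (or VarTD) distribution,
#' which is typically left-skewed for AvTD: mean, population variance,
#' moment skewness `m3 / m2^(3/2)`, and the 2.5/5/50/95/97.5 attained
#' percentiles.
#'
#' @param x a `"replicate_set"` or a numeric vector of replicate values.
#' @param which `"avtd"` or `"vartd"` when `x` is a replicate set.
#' @return a list with `mean`, `variance`, `skewness` and `quantiles`.
#' @export
distribution_summary <- function(x, which = c("avtd", "vartd")) {
  if (inherits(x, "replicate_set")) {
    which <- match.arg(which)
    x <- if (which == "avtd") x$avtd_values else x$vartd_values
  }
  if (length(x) < 2L) stop("need at least 2 replicate values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  list(mean = m,
       variance = m2,
       skewness = if (m2 > 0) m3 / m2^1.5 else 0,
       quantiles = stats::setNames(
         attained_quantile(x, c(0.025, 0.05, 0.5, 0.95, 0.975)),
         c("2.5%", "5%", "50%", "95%", "97.5%")))
}
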