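# FNV-1a 32-bit hash of a string, for the config fingerprint in output
# headers (no cryptographic intent).
fnv1a32 <- function(x) {
  h <- 0x811c9dc5
  for (b in utf8ToInt(x)) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)   # xor on the low byte
    # 32-bit modular multiply by the FNV prime, kept exact in doubles
    h <- (h %% 65536 * 16777619 +
            (h %/% 65536 * 16777619) %% 65536 * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_header <- function(config, seed) {
  cfg <- paste(deparse(config, width.cutoff = 500L), collapse = " ")
  c(paste0("taxrep ", as.character(utils::packageVersion("taxrep"))),
    paste0("seed: ", if (is.null(seed)) "NULL" else seed),
    paste0("config: ", cfg),
    paste0("config_hash: ", fnv1a32(cfg)))
}

write_result_csv <- function(df, file, header_lines) {
  con <- file(file, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste("#", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a CSV written by the run functions
#'
#' Skips the `#` configuration header the run functions prepend.
#'
#' @param file path to a results/funnel/bands CSV.
#' @return a data frame.
#' @export
read_result_csv <- function(file) {
  utils::read.csv(file, comment.char = "#")
}

#' Full representativeness analysis of samples against a master list
#'
#' The end-to-end workflow: for each sample, prune its tree from the master,
#' compute the distinctness summary (AvTD, VarTD, von Euler's imbalance with
#' its extremal anchors) under master-derived step lengths, test it against
#' `k` random subsamples of the same dimension, and tabulate the funnel
#' lines across `s_range`.  Results are returned and, when `outdir` is
#' given, written as two CSV files (`results.csv`, `funnel.csv`) whose `#`
#' headers echo the package version, seed and configuration.
#'
#' @param master a `taxonomy` or path to a master-list file.
#' @param samples named list of OTU-name vectors, or paths to sample files
#'   (names default to file names).
#' @param scheme scheme kind (`"proportional"`, `"equal"`, `"unit"`) or a
#'   `step_lengths` object.
#' @param s_range subsample dimensions for the funnel; defaults to the
#'   sample dimensions.
#' @param k replicates per dimension.
#' @param seed integer seed; recorded in all outputs.
#' @param tail `"one"` or `"two"` for the significance tests.
#' @param outdir optional output directory (created if missing).
#' @return invisibly, a list with `results` (one row per sample: dimension,
#'   AvTD, VarTD, I_E, extremal AvTDs, p-values) and `funnel` (the
#'   [funnel_analysis()] table).
#' @examples
#' m <- synthetic_taxonomy(c(40, 15, 5, 1), seed = 7)
#' run_representativeness(m, list(s1 = otu_names(m)[1:10]),
#'                        k = 50, seed = 7)$results
#' @export
run_representativeness <- function(master, samples, scheme = "proportional",
                                   s_range = NULL, k = 100, seed = NULL,
                                   tail = c("one", "two"), outdir = NULL) {
  tail <- match.arg(tail)
  if (is.character(master)) master <- read_master_list(master)
  if (!is.list(samples)) samples <- list(samples)
  samples <- lapply(samples, function(s) {
    if (length(s) == 1L && file.exists(s)) read_sample(s, master) else s
  })
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  scheme <- resolve_scheme(scheme, master)
  dims <- vapply(samples, length, integer(1))
  if (is.null(s_range)) s_range <- sort(unique(dims))
  config <- list(scheme = scheme$kind, s_range = s_range, k = k,
                 tail = tail, samples = names(samples))

  rows <- with_seed(seed, lapply(names(samples), function(nm) {
    tree <- prune_taxonomy(master, samples[[nm]])
    di <- distinctness(tree, scheme)
    reps <- replicate_set(master, di$s, k = k, scheme = scheme)
    pv <- significance_test(di, reps, tail = tail)
    cbind(data.frame(sample = nm), as.data.frame(di),
          data.frame(p_avtd = pv$p_avtd, p_vartd = pv$p_vartd, tail = tail))
  }))
  results <- do.call(rbind, rows)
  funnel <- funnel_analysis(master, s_range = s_range, k = k,
                            scheme = scheme,
                            seed = if (is.null(seed)) NULL else seed + 1L)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    hdr <- config_header(config, seed)
    write_result_csv(results, file.path(outdir, "results.csv"), hdr)
    write_result_csv(as.data.frame(funnel), file.path(outdir, "funnel.csv"),
                     hdr)
  }
  invisible(list(results = results, funnel = funnel))
}

#' Shuffling (taxonomy-stability) analysis workflow
#'
#' Generates shuffled master lists per the specification, re-runs the funnel
#' analysis on each and aggregates the confidence bands; optionally writes
#' the bands CSV and the shuffled lists themselves.
#'
#' @param master a `taxonomy` or path to a master-list file.
#' @param spec a [shuffle_spec()].
#' @param n_lists number of shuffled master lists.
#' @param s_range subsample dimensions.
#' @param k replicates per dimension per list.
#' @param scheme scheme kind or `step_lengths` object.
#' @param seed integer seed; recorded in all outputs.
#' @param outdir optional output directory for `bands.csv`.
#' @param write_lists if `TRUE`, each shuffled master list is also written
#'   under `outdir/shuffled/`.
#' @return invisibly, the [shuffling_analysis()] bands table.
#' @export
run_shuffle <- function(master, spec, n_lists, s_range, k = 100,
                        scheme = "proportional", seed = NULL, outdir = NULL,
                        write_lists = FALSE) {
  if (is.character(master)) master <- read_master_list(master)
  bands <- shuffling_analysis(master, spec, n_lists = n_lists,
                              s_range = s_range, k = k, scheme = scheme,
                              seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    config <- list(moves = spec$moves, n_lists = n_lists,
                   s_range = s_range, k = k,
                   scheme = attr(bands, "scheme_kind"))
    hdr <- config_header(config, seed)
    write_result_csv(as.data.frame(bands), file.path(outdir, "bands.csv"),
                     hdr)
    if (write_lists) {
      dir.create(file.path(outdir, "shuffled"), showWarnings = FALSE)
      lists <- shuffled_master_lists(master, spec, n_lists,
                                     seed = if (is.null(seed)) NULL
                                            else seed + 1L)
      for (i in seq_along(lists)) {
        write_master_list(lists[[i]],
                          file.path(outdir, "shuffled",
                                    sprintf("master_%04d.csv", i)),
                          header_lines = hdr)
      }
    }
  }
  invisible(bands)
}
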