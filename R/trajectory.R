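#' Build an LZ-normalized fold-change trajectory matrix
#'
#' For each gene and each of the three windows (pause, body, post-PAS),
#' window counts are scaled by the stage's run-on-calibrated
#' normalization factor and expressed as log2 fold change relative to the
#' reference stage (LZ) value of the same window, with a pseudocount:
#' `log2((x_s + pc) / (x_ref + pc))`. Reference-stage columns are
#' identically 0 by construction.
#'
#' @param summaries Named list (stage -> data.frame from
#'   [summarize_genes()]); genes must be present in every stage (genes
#'   missing from any stage are dropped with a message).
#' @param factors A data.frame from [normalization_factors()], or a named
#'   numeric vector of per-stage multiplicative factors.
#' @param pseudocount Pseudocount in normalized-count units (default 1).
#' @param reference Reference stage (default `"LZ"`).
#' @param windows Which windows to use (default all three).
#' @param rescale_factors If `TRUE` (default), rescale the per-stage
#'   factors to geometric mean 1 before applying them, so normalized
#'   counts stay on the scale of raw counts and the pseudocount is
#'   meaningful. A common rescaling of all factors leaves every
#'   cross-stage ratio unchanged.
#' @return A numeric matrix (genes x stage.window columns) with
#'   attributes `stages` and `windows`.
#' @export
build_trajectories <- function(summaries, factors, pseudocount = 1,
                               reference = "LZ",
                               windows = c("pause", "body", "postpas"),
                               rescale_factors = TRUE) {
  stopifnot(is.list(summaries), !is.null(names(summaries)))
  stages <- names(summaries)
  if (!reference %in% stages) stop_input("reference stage not present")
  fac <- if (is.data.frame(factors)) {
    stats::setNames(factors$factor, factors$stage)
  } else factors
  if (!all(stages %in% names(fac))) {
    stop_input("missing normalization factor for stage(s): ",
               paste(setdiff(stages, names(fac)), collapse = ", "))
  }
  if (rescale_factors) {
    fac <- fac / exp(mean(log(fac[stages])))
  }
  common <- Reduce(intersect, lapply(summaries, function(s) s$gene_id))
  dropped <- setdiff(unique(unlist(lapply(summaries, `[[`, "gene_id"))),
                     common)
  if (length(dropped)) {
    message(length(dropped), " gene(s) missing from at least one stage; ",
            "dropped")
  }
  common <- sort(common)
  count_cols <- paste0(windows, "_count")
  ## raw counts x stage factor = normalized counts (counts already carry
  ## the track scale only if tracks were rescaled; factors are applied
  ## here, so summaries should come from unscaled tracks)
  norm <- lapply(stages, function(st) {
    s <- summaries[[st]]
    s <- s[match(common, s$gene_id), ]
    as.matrix(s[, count_cols]) * fac[[st]]
  })
  names(norm) <- stages
  ref <- norm[[reference]]
  cols <- lapply(stages, function(st) {
    log2((norm[[st]] + pseudocount) / (ref + pseudocount))
  })
  M <- do.call(cbind, cols)
  colnames(M) <- unlist(lapply(stages, function(st) paste(st, windows,
                                                          sep = ".")))
  rownames(M) <- common
  attr(M, "stages") <- stages
  attr(M, "windows") <- windows
  attr(M, "reference") <- reference
  M
}

#' Cluster fold-change trajectories into pattern groups
#'
#' Seeded k-means on row-z-scored trajectories, after setting aside
#' near-flat genes (max absolute log2 fold change below `flatness`),
#' which are reported as unassigned. Rows are processed in sorted
#' gene-id order, so assignments are invariant to input row order.
#'
#' @param M Trajectory matrix from [build_trajectories()].
#' @param k Number of clusters (>= 2).
#' @param seed RNG seed for k-means initialisation.
#' @param flatness Flat-gene threshold in log2 units (default 0.25).
#' @param nstart k-means restarts (default 25).
#' @return A list of class `cluster_result`: `assignments` (named integer
#'   vector, `NA` = unassigned/flat), `centroids` (k x ncol(M), means of
#'   the original-scale trajectories), `k`, `sizes`.
#' @export
cluster_trajectories <- function(M, k = 2, seed = 1, flatness = 0.25,
                                 nstart = 25) {
  if (k < 2) stop_input("k must be >= 2")
  M <- M[order(rownames(M)), , drop = FALSE]
  flat <- apply(abs(M), 1, max) < flatness
  act <- M[!flat, , drop = FALSE]
  if (nrow(act) < k) {
    stop_input("fewer non-flat trajectories (", nrow(act),
               ") than clusters (", k, ")")
  }
  z <- t(apply(act, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) r - mean(r) else (r - mean(r)) / s
  }))
  km <- with_seed(seed, stats::kmeans(z, centers = k, nstart = nstart,
                                      iter.max = 100))
  assignments <- stats::setNames(rep(NA_integer_, nrow(M)), rownames(M))
  assignments[rownames(act)] <- km$cluster
  centroids <- t(vapply(seq_len(k), function(cl) {
    colMeans(act[km$cluster == cl, , drop = FALSE])
  }, numeric(ncol(M))))
  colnames(centroids) <- colnames(M)
  structure(list(assignments = assignments, centroids = centroids,
                 k = k, sizes = as.integer(table(factor(km$cluster,
                                                        levels = 1:k)))),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d; sizes = %s; unassigned = %d\n",
              x$k, paste(x$sizes, collapse = ", "),
              sum(is.na(x$assignments))))
  invisible(x)
}

#' Per-cluster pausing-index summaries by stage
#'
#' Median and quartiles of the pausing index for each cluster at each
#' stage, for contrasting pattern groups (e.g. a pachytene-burst cluster
#' against a steady-state cluster). Formal paired tests are left to
#' standard routines such as [stats::wilcox.test()].
#'
#' @param clusters A [cluster_trajectories()] result.
#' @param pi_table Long table from [pausing_index_table()].
#' @return A data.frame: `cluster`, `stage`, `n`, `median`, `q25`, `q75`.
#' @export
pattern_pi_contrast <- function(clusters, pi_table) {
  stopifnot(inherits(clusters, "cluster_result"))
  asg <- clusters$assignments
  out <- list()
  for (cl in seq_len(clusters$k)) {
    ids <- names(asg)[!is.na(asg) & asg == cl]
    sub <- pi_table[pi_table$gene_id %in% ids, ]
    for (st in levels(pi_table$stage)) {
      v <- sub$pausing_index[sub$stage == st]
      v <- v[!is.na(v)]
      out[[length(out) + 1]] <- data.frame(
        cluster = cl, stage = st, n = length(v),
        median = if (length(v)) stats::median(v) else NA_real_,
        q25 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
        q75 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Concordance between nascent transcription and mRNA abundance
#'
#' Ordinary least-squares slope and Pearson correlation between two
#' per-gene measurements on a log2 scale with a pseudocount: a slope
#' below 1 indicates compression of mRNA differences relative to nascent
#' transcription (or vice versa, depending on orientation).
#'
#' @param x,y Per-gene values (e.g. nascent counts and mRNA counts).
#' @param pseudocount Added before the log transform (default 1).
#' @param log Transform with `log2(v + pseudocount)` (default). Set
#'   `FALSE` if the inputs are already in log space.
#' @return A list: `slope`, `intercept`, `r`, `n`.
#' @export
concordance <- function(x, y, pseudocount = 1, log = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_input("need at least 3 paired values")
  if (log) {
    x <- log2(x + pseudocount); y <- log2(y + pseudocount)
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y), n = length(x))
}
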