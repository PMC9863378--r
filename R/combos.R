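#' Enumerate uncorrelated descriptor combinations
#'
#' Recursive correlation splitting: whenever two candidate descriptors have a
#' squared Pearson correlation strictly greater than `r2_threshold` (computed
#' on per-compound rows; descriptors are constant across replicates), the
#' candidate set branches into two subsets, each dropping one endpoint of the
#' correlated pair.  Branching continues until every subset is pairwise
#' uncorrelated; duplicated and non-maximal subsets are then removed.  The
#' result equals the set of maximal independent sets of the graph whose edges
#' join descriptor pairs with R-squared above the threshold.
#'
#' @param xs A `scaled_matrix`.
#' @param candidates Character vector of descriptor codes (typically the
#'   ANN-selected set).
#' @param r2_threshold Squared-correlation threshold (default 0.5); ties at
#'   exactly the threshold do not branch.
#' @return A `combination_list`: `sets` (list of code vectors, largest first)
#'   and `r2_threshold`.
#' @export
enumerate_uncorrelated <- function(xs, candidates, r2_threshold = 0.5) {
  stopifnot(inherits(xs, "scaled_matrix"))
  if (length(candidates) == 0L) {
    return(structure(list(sets = list(), r2_threshold = r2_threshold),
                     class = "combination_list"))
  }
  unknown <- setdiff(candidates, colnames(xs$values))
  if (length(unknown)) {
    stop("unknown descriptor(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  candidates <- unique(candidates)
  r2 <- stats::cor(xs$values[, candidates, drop = FALSE])^2
  adj <- r2 > r2_threshold
  diag(adj) <- FALSE

  memo <- new.env(parent = emptyenv())
  recurse <- function(idx) {
    key <- paste(idx, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    sub <- adj[idx, idx, drop = FALSE]
    hit <- which(sub, arr.ind = TRUE)
    res <- if (nrow(hit) == 0L) {
      list(idx)
    } else {
      i <- idx[hit[1L, 1L]]; j <- idx[hit[1L, 2L]]
      c(recurse(setdiff(idx, i)), recurse(setdiff(idx, j)))
    }
    memo[[key]] <- res
    res
  }
  dedup_maximal <- function(sets) {
    sets <- unique(lapply(sets, sort))
    keep <- vapply(seq_along(sets), function(i) {
      !any(vapply(seq_along(sets), function(j) {
        i != j && length(sets[[i]]) < length(sets[[j]]) &&
          all(sets[[i]] %in% sets[[j]])
      }, logical(1)))
    }, logical(1))
    sets[keep]
  }
  # correlated pairs never straddle connected components of the conflict
  # graph, so splitting factorises: enumerate maximal subsets per component
  # and take all cross-unions (identical result, far fewer recursions)
  n <- length(candidates)
  comp <- integer(n)
  cid <- 0L
  for (s0 in seq_len(n)) {
    if (comp[s0]) next
    cid <- cid + 1L
    queue <- s0
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v]) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  per_comp <- lapply(seq_len(cid), function(k) {
    dedup_maximal(recurse(which(comp == k)))
  })
  sets <- Reduce(function(acc, cs) {
    unlist(lapply(acc, function(a) lapply(cs, function(b) c(a, b))),
           recursive = FALSE)
  }, per_comp, accumulate = FALSE, init = list(integer(0)))
  sets <- lapply(sets, function(i) candidates[sort(i)])
  ord <- order(-lengths(sets),
               vapply(sets, function(s) paste(s, collapse = "|"), ""))
  structure(list(sets = sets[ord], r2_threshold = r2_threshold),
            class = "combination_list")
}

#' @export
print.combination_list <- function(x, ...) {
  cat("combination_list:", length(x$sets),
      sprintf("uncorrelated descriptor set(s) at R2 <= %g\n", x$r2_threshold))
  invisible(x)
}
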