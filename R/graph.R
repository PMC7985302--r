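## Partial-frequency-coupling graphs: PGC edge weights with pairwise MIF
## stored alongside, control-derived thresholds, and motif classification.

## bootstrap SD of an estimate: classifier -> SD of the bootstrap trace;
## knn -> SD over deterministic half-sample subsets (knn has no trace).
.estimateSD <- function(est, fx, fy, fz, k) {
  tr <- bootstrapTrace(est)
  if (estimatorName(est) == "classifier" && length(tr) > 1L)
    return(sd(tr) / sqrt(length(tr)))
  N <- nrow(fx)
  half <- floor(N / 2)
  vals <- vapply(1:10, function(i) {
    idx <- seq.int(((i - 1L) %% 2L) + 1L, N, by = 2L)  # alternating halves
    idx <- ((idx + i * 97L) %% N) + 1L                  # deterministic spread
    t1 <- couplingValue(knnMI(fx[idx, , drop = FALSE],
                              cbind(fy, fz)[idx, , drop = FALSE], k = k))
    t2 <- couplingValue(knnMI(fx[idx, , drop = FALSE],
                              fz[idx, , drop = FALSE], k = k))
    t1 - t2
  }, numeric(1))
  sd(vals)
}

#' Build a partial-frequency-coupling graph
#'
#' For every unordered pair of declared vertices, estimates the PGC between
#' the two nodes' increment sets conditioned (by default) on all remaining
#' declared increments, together with the pairwise MIF. An edge is kept iff
#' its PGC weight exceeds the threshold tau. When `tau` is NULL a per-pair
#' threshold is derived from a control PGC (conditioning on
#' `controlFreqs`): tau = control mean + 3 * control bootstrap SD.
#'
#' @param sampleset a [SpectralSampleSet-class] containing every declared
#'   increment (and `controlFreqs` when used).
#' @param nodes named list: vertex (channel) name -> declared frequencies
#'   (Hz).
#' @param tau edge threshold in nats, or NULL to derive per-pair thresholds
#'   from controls.
#' @param controlFreqs irrelevant frequencies used for control-derived
#'   thresholds (required when `tau` is NULL).
#' @param estimator "auto", "classifier" or "knn".
#' @param cspec,bspec,k,seed estimator configuration as in [pgcQuery()].
#' @param dimBudget cap on the conditioning dimension (columns); increments
#'   beyond the budget are dropped with a warning.
#' @return A [PGCGraph-class].
#' @export
buildPGCGraph <- function(sampleset, nodes, tau = NULL, controlFreqs = NULL,
                          estimator = "auto", cspec = classifierSpec(),
                          bspec = bootstrapSpec(), k = 5, seed = 1,
                          dimBudget = 12) {
  if (length(nodes) < 2L) stop("need at least 2 vertices", call. = FALSE)
  if (is.null(tau) && is.null(controlFreqs))
    stop("either a fixed tau or controlFreqs for control-derived thresholds is required",
         call. = FALSE)
  vs <- names(nodes)
  combs <- utils::combn(vs, 2L, simplify = FALSE)
  rows <- lapply(combs, function(pr) {
    a <- pr[1L]; b <- pr[2L]
    others <- setdiff(vs, pr)
    condCh <- unlist(lapply(others, function(v) rep(v, length(nodes[[v]]))))
    condFr <- unlist(nodes[others])
    if (2L * length(condCh) > dimBudget) {
      keep <- seq_len(dimBudget %/% 2L)
      warning(sprintf("pair %s-%s: conditioning truncated to %d increments by dimBudget",
                      a, b, length(keep)))
      condCh <- condCh[keep]; condFr <- condFr[keep]
    }
    q <- pgcQuery(incrementSelection(a, nodes[[a]]),
                  incrementSelection(b, nodes[[b]]),
                  cond = incrementSelection(condCh, condFr),
                  estimator = estimator, cspec = cspec, bspec = bspec,
                  k = k, seed = seed)
    ok <- TRUE
    pgcEst <- tryCatch(pgc(q, sampleset), error = function(e) {
      ok <<- FALSE; NULL
    })
    mifEst <- tryCatch(mif(q, sampleset), error = function(e) {
      ok <<- FALSE; NULL
    })
    ctrlVal <- NA_real_
    tauPair <- if (!is.null(tau)) tau else NA_real_
    if (ok && is.null(tau)) {
      ctrl <- controlPGC(q, sampleset, controlFreqs)
      ctrlVal <- couplingValue(ctrl)
      fx <- selectIncrements(sampleset, q@xSel)
      fy <- selectIncrements(sampleset, q@ySel)
      fc <- selectIncrements(sampleset,
                             incrementSelection(rep(unique(condCh),
                                                    each = length(controlFreqs)),
                                                rep(controlFreqs,
                                                    times = length(unique(condCh)))))
      tauPair <- ctrlVal + 3 * .estimateSD(ctrl, fx, fy, fc, k)
    }
    data.frame(from = a, to = b,
               pgc = if (ok) couplingValue(pgcEst) else NA_real_,
               mif = if (ok) couplingValue(mifEst) else NA_real_,
               control = ctrlVal, tau = tauPair, ok = ok)
  })
  pairs <- do.call(rbind, rows)
  new("PGCGraph", vertices = vs, pairs = pairs,
      tau = if (is.null(tau)) mean(pairs$tau, na.rm = TRUE) else tau,
      nodeFreqs = nodes,
      meta = list(estimator = estimator, seed = seed,
                  controlFreqs = controlFreqs))
}

#' Classify pairwise motifs from MIF and PGC together
#'
#' Pairwise and partial measures must be read jointly: a proxy or
#' common-input link shows high MIF but vanishing PGC (indirect), while a
#' collider shows vanishing MIF but non-zero PGC (conditioning on a common
#' effect induces dependence). Pairs are classified per stored values:
#' direct (both above tau), indirect (MIF high, PGC low), collider-suspect
#' (MIF low, PGC high), independent (both low).
#'
#' @param graph a [PGCGraph-class] carrying MIF and PGC per pair.
#' @return data.frame: from, to, mif, pgc, tau, label.
#' @export
motifReport <- function(graph) {
  stopifnot(is(graph, "PGCGraph"))
  p <- graph@pairs
  lab <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    if (!p$ok[i] || is.na(p$mif[i]) || is.na(p$pgc[i])) {
      lab[i] <- "unclassifiable"; next
    }
    mifHigh <- p$mif[i] > p$tau[i]
    pgcHigh <- p$pgc[i] > p$tau[i]
    lab[i] <- if (mifHigh && pgcHigh) "direct"
      else if (mifHigh && !pgcHigh) "indirect"
      else if (!mifHigh && pgcHigh) "collider-suspect"
      else "independent"
  }
  data.frame(from = p$from, to = p$to, mif = p$mif, pgc = p$pgc,
             tau = p$tau, label = lab)
}

#' Convert a PGCGraph to an igraph object
#'
#' Thresholded edges only, with `pgc` (weight), `mif` and `tau` edge
#' attributes.
#'
#' @param graph a [PGCGraph-class].
#' @return An [igraph::graph] (undirected, weighted).
#' @export
asIgraph <- function(graph) {
  stopifnot(is(graph, "PGCGraph"))
  e <- graphEdges(graph)
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = graph@vertices)
  if (nrow(e)) igraph::E(g)$weight <- e$pgc
  g
}

#' Export a PGCGraph
#'
#' `writeGraphML()` writes the thresholded graph in GraphML;
#' `writeGraphEdges()` writes the full per-pair table (including sub-
#' threshold pairs) as CSV. Weights are in nats.
#'
#' @param graph a [PGCGraph-class].
#' @param path output file path.
#' @export
writeGraphML <- function(graph, path) {
  igraph::write_graph(asIgraph(graph), path, format = "graphml")
  invisible(path)
}

#' @rdname writeGraphML
#' @export
writeGraphEdges <- function(graph, path) {
  write.csv(graph@pairs, path, row.names = FALSE)
  invisible(path)
}
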