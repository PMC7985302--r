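## End-to-end recipes on synthetic data, used by the `figure` CLI
## subcommand. Scaled-down defaults (4000 trials, 10-20 bootstrap
## iterations, 20 benchmark simulations) so each recipe runs on one CPU in
## minutes; larger settings are reachable through the flags of the calling
## subcommand or by calling the underlying functions directly.

.writeHeatmapPDF <- function(mat, path, main) {
  grDevices::pdf(path, width = 5, height = 4.5)
  on.exit(grDevices::dev.off())
  n <- nrow(mat)
  graphics::image(seq_len(n), seq_len(n), t(mat[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "", main = main,
                  col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE))
  graphics::axis(1, seq_len(n), colnames(mat))
  graphics::axis(2, seq_len(n), rev(rownames(mat)), las = 2)
  for (i in seq_len(n)) for (j in seq_len(n))
    graphics::text(j, n + 1 - i, sprintf("%.2f", mat[i, j]), cex = 0.9)
}

## Pairwise + partial coupling tables for the linear three-process network,
## estimated (coherence path and classifier MIF/PGC) and analytic.
.recipeLinear <- function(outDir, seed = 1, nTrials = 4000, iterations = 20) {
  cfg <- linearSimConfig(nTrials = nTrials, seed = seed)
  ts <- simulateLinear(cfg)
  sss <- sampleIncrements(ts, frequencies = cfg@f0)
  truth <- analyticLinearFC(cfg)
  csm <- estimateCrossSpectralMatrix(sss, c("X", "W", "Z"), cfg@f0)
  chans <- c("X", "W", "Z")
  mk <- function() matrix(0, 3, 3, dimnames = list(chans, chans))
  cohM <- mk(); mifM <- mk(); pcohM <- mk(); pgcM <- mk(); truthM <- mk()
  truthP <- mk()
  bspec <- bootstrapSpec(iterations = iterations)
  for (i in 1:2) for (j in (i + 1):3) {
    a <- chans[i]; b <- chans[j]
    cohM[i, j] <- cohM[j, i] <- miFromCoherence(coherence(csm, a, b))
    pcohM[i, j] <- pcohM[j, i] <- miFromCoherence(partialCoherence(csm, a, b))
    q <- pgcQuery(incrementSelection(a, cfg@f0), incrementSelection(b, cfg@f0),
                  cond = incrementSelection(setdiff(chans, c(a, b)), cfg@f0),
                  estimator = "classifier", bspec = bspec, seed = seed)
    mifM[i, j] <- mifM[j, i] <- couplingValue(mif(q, sss))
    pgcM[i, j] <- pgcM[j, i] <- couplingValue(pgc(q, sss))
    row <- truth[truth$pair %in% paste(c(a, b), c(b, a), sep = "-"), ]
    truthM[i, j] <- truthM[j, i] <- row$mif
    truthP[i, j] <- truthP[j, i] <- row$pgc
  }
  tabs <- list(fc_coherence = cohM, fc_mif = mifM, fc_analytic = truthM,
               partial_coherence = pcohM, partial_pgc = pgcM,
               partial_analytic = truthP)
  for (nm in names(tabs)) {
    write.csv(tabs[[nm]], file.path(outDir, paste0(nm, ".csv")))
    .writeHeatmapPDF(tabs[[nm]], file.path(outDir, paste0(nm, ".pdf")), nm)
  }
  .cliLog("linear recipe written to %s", outDir)
  0L
}

## MIF / control-PGC / relevant-PGC tables for the nonlinear network: the
## eight coupling cells of the common-input motif with f0 = 2 Hz.
.recipeNonlinear <- function(outDir, seed = 1, nTrials = 4000,
                             iterations = 10) {
  cfg <- nonlinearSimConfig(nTrials = nTrials, seed = seed)
  f0 <- cfg@f0
  sss <- sampleIncrements(ts <- simulateNonlinear(cfg),
                          frequencies = c(0, 1, f0, 3, 2 * f0, 3 * f0))
  bspec <- bootstrapSpec(iterations = iterations)
  ## coupling cells: (channel a, freq fa) x (channel b, freq fb) with the
  ## relevant conditioning set (third channel at its informative bins) and
  ## the control conditioning (uninformative bins of that channel)
  cells <- list(
    list("X", f0, "W", 0,      "Z", c(f0, 3 * f0), c(1, 3)),
    list("X", f0, "W", 2 * f0, "Z", c(f0, 3 * f0), c(1, 3)),
    list("X", f0, "Z", f0,     "W", c(0, 2 * f0),  c(1, 3)),
    list("X", f0, "Z", 3 * f0, "W", c(0, 2 * f0),  c(1, 3)),
    list("W", 0,      "Z", f0,     "X", f0, 1),
    list("W", 0,      "Z", 3 * f0, "X", f0, 1),
    list("W", 2 * f0, "Z", f0,     "X", f0, 1),
    list("W", 2 * f0, "Z", 3 * f0, "X", f0, 1))
  rows <- lapply(cells, function(cl) {
    q <- pgcQuery(incrementSelection(cl[[1]], cl[[2]]),
                  incrementSelection(cl[[3]], cl[[4]]),
                  cond = incrementSelection(cl[[5]], cl[[6]]),
                  estimator = "classifier", bspec = bspec, seed = seed)
    data.frame(pair = sprintf("%s@%g-%s@%g", cl[[1]], cl[[2]], cl[[3]],
                              cl[[4]]),
               mif = couplingValue(mif(q, sss)),
               controlPGC = couplingValue(controlPGC(q, sss, cl[[7]])),
               pgc = couplingValue(pgc(q, sss)))
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(outDir, "nonlinear_coupling.csv"),
            row.names = FALSE)
  .cliLog("nonlinear recipe written to %s", outDir)
  0L
}

## Scaled-down scaling study: 12-d PGC and 4-d MIF problems.
.recipeScaling <- function(outDir, seed = 1, nSims = 20) {
  tab12 <- runBenchmark(benchmarkDesign("pgc_12d", nSims = nSims,
                                        seed = seed))
  tab4 <- runBenchmark(benchmarkDesign("mif_4d", nSims = nSims, seed = seed))
  tab <- rbind(tab12, tab4)
  write.csv(tab, file.path(outDir, "scaling_benchmark.csv"),
            row.names = FALSE)
  grDevices::pdf(file.path(outDir, "scaling_benchmark.pdf"), width = 7,
                 height = 4)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  for (pb in c("pgc_12d", "mif_4d")) {
    sub <- tab[tab$problem == pb, ]
    cl <- sub[sub$estimator == "classifier", ]
    kn <- sub[sub$estimator == "knn", ]
    plot(cl$N, cl$meanAbsError, type = "b", log = "x", xlab = "N",
         ylab = "mean |error| (nats)", ylim = range(sub$meanAbsError),
         main = pb)
    graphics::lines(kn$N, kn$meanAbsError, type = "b", lty = 2)
    graphics::legend("topright", c("classifier", "k-nn"), lty = 1:2,
                     bty = "n")
  }
  .cliLog("scaling recipe written to %s", outDir)
  0L
}
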