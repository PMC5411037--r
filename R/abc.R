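#' Build an ABC reference table
#'
#' Draws parameters from each scenario's priors and simulates the summary
#' statistics through the fast coalescent path, storing one row per
#' simulated dataset. Equal numbers of rows per scenario give the scenarios
#' equal prior weight.
#'
#' @param specs list of \linkS4class{ScenarioSpec} objects.
#' @param nPerScenario rows simulated per scenario.
#' @param nATL,nMED,mtATL,mtMED,seqLen,L sampling design (see
#'   \code{\link{simulateScenario}}).
#' @param tsRatio,msatModel,pStep,varMultiStep mutation-model settings.
#' @param seed optional integer seed.
#' @return a \linkS4class{ReferenceTable}.
#' @export
buildReferenceTable <- function(specs, nPerScenario = 1e4, nATL = 85,
                                nMED = 97, mtATL = 48, mtMED = 66,
                                seqLen = 613, L = 9, tsRatio = 2,
                                msatModel = c("SMM", "TPM"), pStep = 0.8,
                                varMultiStep = 20, seed = NULL) {
  msatModel <- match.arg(msatModel)
  maybeSeed(seed)
  geomQ <- geomParamFromVar(varMultiStep)
  modelInt <- if (msatModel == "SMM") 0L else 1L
  nTot <- length(specs) * nPerScenario
  parNames <- c("NATL", "NMED", "NbATL", "NbMED", "t", "t1", "Nanc",
                "muMsatMean", "muMt")
  params <- matrix(NA_real_, nTot, length(parNames),
                   dimnames = list(NULL, parNames))
  stats <- matrix(NA_real_, nTot, 18,
                  dimnames = list(NULL, summaryStatNames()))
  scen <- integer(nTot)
  r <- 0L
  for (spec in specs) {
    for (i in seq_len(nPerScenario)) {
      r <- r + 1L
      d <- drawPriorParameters(spec, L = L)
      res <- .cppSimulateScenario(d$NATL, d$NMED, d$NbATL, d$NbMED, d$t,
        d$t1, d$Nanc, d$muMsat, d$muMt, as.integer(nATL),
        as.integer(nMED), as.integer(mtATL), as.integer(mtMED),
        as.integer(seqLen), tsRatio, modelInt, pStep, geomQ, FALSE)
      params[r, ] <- c(d$NATL, d$NMED, d$NbATL, d$NbMED, d$t, d$t1,
                       d$Nanc, d$muMsatMean, d$muMt)
      stats[r, ] <- res$stats
      scen[r] <- spec@scenario
    }
  }
  new("ReferenceTable", scenario = scen, params = params, stats = stats,
      specs = specs,
      design = list(nATL = nATL, nMED = nMED, mtATL = mtATL,
                    mtMED = mtMED, seqLen = seqLen, L = L,
                    tsRatio = tsRatio, msatModel = msatModel,
                    pStep = pStep, varMultiStep = varMultiStep))
}

#' Summary statistics held out of the ABC distance by default
#'
#' The remaining statistics drive the rejection/regression steps; the
#' held-out ones are reserved for posterior-predictive model checking.
#' @return character vector of statistic names.
#' @export
defaultHoldoutStats <- function()
  c("ATL_TAJD", "MED_TAJD", "DAS", "SHARED")

# Standardize columns by reference mean/sd; NA entries (masked undefined
# components) become 0 after centering, i.e. they carry no distance.
standardizeStats <- function(refStats, useStats, extra = NULL) {
  mu <- apply(refStats[, useStats, drop = FALSE], 2, mean, na.rm = TRUE)
  sdv <- apply(refStats[, useStats, drop = FALSE], 2, sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  std <- function(m) {
    z <- sweep(sweep(m[, useStats, drop = FALSE], 2, mu), 2, sdv, "/")
    z[is.na(z)] <- 0
    z
  }
  out <- list(ref = std(refStats))
  if (!is.null(extra))
    out$extra <- std(matrix(extra, nrow = 1,
                            dimnames = list(NULL, names(extra))))
  out
}

#' ABC model choice by rejection and multinomial logistic regression
#'
#' Standardizes the summary statistics by the reference-table mean and
#' standard deviation, retains the fraction of rows closest to the
#' observed vector in Euclidean distance, and fits a multinomial logistic
#' regression of scenario id on the (centred) summaries within the
#' retained set; posterior probabilities are the fit evaluated at the
#' observed point. Plain rejection proportions are reported alongside, and
#' a bootstrap of the retained set gives confidence intervals when
#' \code{nBoot > 0}.
#'
#' @param ref a ReferenceTable.
#' @param observed named summary vector (as from
#'   \code{\link{summaryStatistics}}).
#' @param retainedFraction fraction of rows retained (paper-style 0.01).
#' @param useStats statistics used for the distance and regression.
#' @param nBoot bootstrap replicates for the CI (0 to skip).
#' @return list with \code{probabilities} (named by scenario),
#'   \code{rejection} (retained-set proportions), \code{ci} (2.5/97.5
#'   bootstrap quantiles or NULL), \code{nRetained}.
#' @export
abcModelChoice <- function(ref, observed, retainedFraction = 0.01,
                           useStats = setdiff(summaryStatNames(),
                                              defaultHoldoutStats()),
                           nBoot = 0) {
  sc <- sort(unique(ref@scenario))
  z <- standardizeStats(ref@stats, useStats, observed)
  d <- sqrt(rowSums(sweep(z$ref, 2, as.numeric(z$extra))^2))
  k <- max(length(sc) + 1L, ceiling(retainedFraction * nrow(z$ref)))
  idx <- order(d)[seq_len(k)]
  yy <- factor(ref@scenario[idx], levels = sc)
  rej <- as.numeric(table(yy)) / length(idx)
  names(rej) <- paste0("scenario", sc)
  miss <- sc[!(sc %in% unique(ref@scenario[idx]))]
  if (length(miss))
    warning("scenario(s) absent from retained set: ",
            paste(miss, collapse = ", "))
  fitProbs <- function(rows) {
    y <- droplevels(factor(ref@scenario[rows], levels = sc))
    pr <- setNames(numeric(length(sc)), as.character(sc))
    if (nlevels(y) < 2L) {
      pr[levels(y)] <- 1
      return(unname(pr))
    }
    X <- z$ref[rows, , drop = FALSE]
    X <- sweep(X, 2, as.numeric(z$extra))
    df <- data.frame(y = y, X)
    fit <- nnet::multinom(y ~ ., data = df, trace = FALSE,
                          maxit = 200, MaxNWts = 5000)
    nd <- as.data.frame(matrix(0, 1, ncol(X)))
    names(nd) <- colnames(df)[-1]
    p1 <- predict(fit, newdata = nd, type = "probs")
    if (is.null(dim(p1)) && length(p1) == 1) {
      pr[levels(y)] <- c(1 - p1, p1)
    } else {
      p1 <- drop(p1)
      pr[names(p1)] <- p1
    }
    unname(pr)
  }
  probs <- fitProbs(idx)
  names(probs) <- paste0("scenario", sc)
  ci <- NULL
  if (nBoot > 0) {
    bp <- replicate(nBoot,
      fitProbs(sample(idx, length(idx), replace = TRUE)))
    ci <- apply(bp, 1, quantile, probs = c(0.025, 0.975))
    colnames(ci) <- names(probs)
  }
  list(probabilities = probs, rejection = rej, ci = ci,
       nRetained = length(idx))
}

weightedQuantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], 0)
}

#' ABC parameter posteriors by local-linear regression on the logit scale
#'
#' Restricts the reference table to the chosen scenario, retains the rows
#' closest to the observed summaries, transforms each parameter to the
#' logit of its position within its prior bounds, regresses the
#' transformed draws on the (centred) summaries with Epanechnikov weights,
#' keeps the fit at the observed point plus residuals, and back-transforms
#' -- so every adjusted draw stays inside the prior support. The mode is
#' the back-transformed argmax of a weighted Gaussian KDE (Silverman
#' bandwidth) on the transformed scale. A singular regression falls back
#' to the rejection-only posterior with a warning.
#'
#' @param ref a ReferenceTable.
#' @param observed named summary vector.
#' @param scenario scenario id to condition on.
#' @param nRetain number of retained rows (paper-style 10000); capped at
#'   the number of scenario rows.
#' @param parameters parameters to summarize; defaults to the parameters
#'   free under the scenario.
#' @param useStats statistics used for the distance/regression.
#' @param method "loclinear" or "rejection".
#' @return a \linkS4class{PosteriorSummary}.
#' @export
abcParameterPosterior <- function(ref, observed, scenario,
                                  nRetain = 10000, parameters = NULL,
                                  useStats = setdiff(summaryStatNames(),
                                    defaultHoldoutStats()),
                                  method = c("loclinear", "rejection")) {
  method <- match.arg(method)
  rows <- which(ref@scenario == scenario)
  if (!length(rows)) stop("no rows for scenario ", scenario)
  spec <- NULL
  for (s in ref@specs) if (s@scenario == scenario) spec <- s
  if (is.null(spec)) stop("spec for scenario ", scenario, " not stored")
  if (is.null(parameters)) {
    parameters <- switch(scenario,
      c("NATL", "NMED", "t"),
      c("NATL", "NMED", "t", "t1", "NbMED"),
      c("NATL", "NMED", "t", "t1", "NbATL"),
      c("NATL", "NMED", "t", "t1", "NbATL", "NbMED"))
  }
  z <- standardizeStats(ref@stats[rows, , drop = FALSE], useStats,
                        observed)
  d <- sqrt(rowSums(sweep(z$ref, 2, as.numeric(z$extra))^2))
  k <- min(nRetain, length(rows))
  sel <- order(d)[seq_len(k)]
  dmax <- max(d[sel])
  w <- 1 - (d[sel] / (dmax * (1 + 1e-12)))^2
  w[w <= 0] <- min(w[w > 0])
  X <- sweep(z$ref[sel, , drop = FALSE], 2, as.numeric(z$extra))
  draws <- matrix(NA_real_, k, length(parameters),
                  dimnames = list(NULL, parameters))
  for (pm in parameters) {
    b <- priorBoundsFor(spec, pm)
    x <- ref@params[rows[sel], pm]
    eps <- (b[2] - b[1]) * 1e-9
    x <- pmin(pmax(x, b[1] + eps), b[2] - eps)
    zx <- log((x - b[1]) / (b[2] - x))
    if (method == "loclinear") {
      fit <- tryCatch(lm(zx ~ X, weights = w), error = function(e) NULL)
      if (is.null(fit) || anyNA(coef(fit)[1])) {
        warning("singular regression: falling back to rejection")
        adj <- zx
      } else {
        adj <- coef(fit)[1] + residuals(fit)
      }
    } else adj <- zx
    draws[, pm] <- (b[1] + b[2] * exp(adj)) / (1 + exp(adj))
  }
  np <- length(parameters)
  summ <- data.frame(mean = rep(NA_real_, np), median = rep(NA_real_, np),
                     mode = rep(NA_real_, np), q025 = rep(NA_real_, np),
                     q975 = rep(NA_real_, np), row.names = parameters)
  for (pm in parameters) {
    x <- draws[, pm]
    b <- priorBoundsFor(spec, pm)
    zx <- log((x - b[1]) / (b[2] - x))
    # Silverman bandwidth from the weighted sd and effective sample size
    wn <- w / sum(w)
    mu <- sum(wn * zx)
    sdw <- sqrt(sum(wn * (zx - mu)^2))
    iqrw <- diff(weightedQuantile(zx, w, c(0.25, 0.75)))
    neff <- 1 / sum(wn^2)
    bw <- 0.9 * min(sdw, iqrw / 1.34) * neff^(-0.2)
    if (!is.finite(bw) || bw <= 0) bw <- max(sdw, 1e-3)
    dens <- density(zx, weights = wn, bw = bw)
    zmode <- dens$x[which.max(dens$y)]
    summ[pm, ] <- c(weighted.mean(x, w),
                    weightedQuantile(x, w, 0.5),
                    (b[1] + b[2] * exp(zmode)) / (1 + exp(zmode)),
                    weightedQuantile(x, w, 0.025),
                    weightedQuantile(x, w, 0.975))
  }
  new("PosteriorSummary", summary = summ, draws = draws, weights = w,
      scenario = as.integer(scenario), method = method)
}

priorBoundsFor <- function(spec, pm) {
  if (pm %in% names(spec@priors)) return(spec@priors[[pm]])
  if (pm == "muMsatMean") return(spec@muMsatPrior)
  if (pm == "muMt") return(spec@muMtPrior)
  stop("unknown parameter ", pm)
}

#' Type I and type II error rates of the scenario choice
#'
#' Simulates pseudo-observed datasets (pods) from each competing scenario,
#' classifies each with \code{\link{abcModelChoice}}, and reports, for the
#' focal scenario, the type I error (simulated from it but not selected)
#' and type II error (simulated from another scenario but selected), plus
#' the full confusion matrix.
#'
#' @param ref a ReferenceTable.
#' @param focalScenario scenario whose errors are reported.
#' @param nPods pods per scenario.
#' @param retainedFraction passed to the classifier.
#' @param method "mnlogistic" (regression, paper-style) or "rejection"
#'   (retained-set majority; faster).
#' @param seed optional integer seed.
#' @return list with \code{typeI}, \code{typeII}, \code{confusion}
#'   (true scenario x selected scenario counts).
#' @export
abcConfidence <- function(ref, focalScenario = 4, nPods = 100,
                          retainedFraction = 0.01,
                          method = c("mnlogistic", "rejection"),
                          seed = NULL) {
  method <- match.arg(method)
  if (nPods < 1) stop("nPods must be positive")
  maybeSeed(seed)
  de <- ref@design
  sc <- sort(unique(ref@scenario))
  geomQ <- geomParamFromVar(de$varMultiStep)
  modelInt <- if (de$msatModel == "SMM") 0L else 1L
  confusion <- matrix(0L, length(sc), length(sc),
                      dimnames = list(true = sc, selected = sc))
  for (spec in ref@specs) {
    for (i in seq_len(nPods)) {
      dr <- drawPriorParameters(spec, L = de$L)
      pod <- .cppSimulateScenario(dr$NATL, dr$NMED, dr$NbATL, dr$NbMED,
        dr$t, dr$t1, dr$Nanc, dr$muMsat, dr$muMt, de$nATL, de$nMED,
        de$mtATL, de$mtMED, de$seqLen, de$tsRatio, modelInt, de$pStep,
        geomQ, FALSE)$stats
      names(pod) <- summaryStatNames()
      selected <- if (method == "mnlogistic") {
        pr <- abcModelChoice(ref, pod, retainedFraction)$probabilities
        sc[which.max(pr)]
      } else {
        rej <- abcModelChoice0(ref, pod, retainedFraction)
        sc[which.max(rej)]
      }
      confusion[as.character(spec@scenario), as.character(selected)] <-
        confusion[as.character(spec@scenario), as.character(selected)] + 1L
    }
  }
  f <- as.character(focalScenario)
  typeI <- 1 - confusion[f, f] / sum(confusion[f, ])
  others <- setdiff(rownames(confusion), f)
  typeII <- sum(confusion[others, f]) / sum(confusion[others, ])
  list(typeI = typeI, typeII = typeII, confusion = confusion)
}

# rejection-only scenario proportions (no regression), internal fast path
abcModelChoice0 <- function(ref, observed, retainedFraction = 0.01,
                            useStats = setdiff(summaryStatNames(),
                                               defaultHoldoutStats())) {
  sc <- sort(unique(ref@scenario))
  z <- standardizeStats(ref@stats, useStats, observed)
  d <- sqrt(rowSums(sweep(z$ref, 2, as.numeric(z$extra))^2))
  k <- max(length(sc), ceiling(retainedFraction * nrow(z$ref)))
  idx <- order(d)[seq_len(k)]
  as.numeric(table(factor(ref@scenario[idx], levels = sc))) / k
}

#' Posterior-predictive model check
#'
#' Draws parameter vectors from the (weighted) rejection posterior of the
#' chosen scenario, simulates new datasets, and reports for each held-out
#' summary statistic the lower-tail posterior-predictive probability
#' P(simulated <= observed); values near 0 or 1 flag misfit. PCA
#' coordinates of the simulated cloud (all statistics, standardized) and
#' of the observed point are returned for the usual overlay plot.
#'
#' @param ref a ReferenceTable.
#' @param observed named summary vector.
#' @param scenario scenario id.
#' @param nSim posterior-predictive simulations.
#' @param nRetain retained rows defining the rejection posterior.
#' @param holdout statistics to check (default
#'   \code{\link{defaultHoldoutStats}}).
#' @param seed optional integer seed.
#' @return list with \code{ppp} (named tail probabilities),
#'   \code{pcaSim} (nSim x 2), \code{pcaObs} (length-2 vector).
#' @export
abcModelCheck <- function(ref, observed, scenario, nSim = 500,
                          nRetain = 5000,
                          holdout = defaultHoldoutStats(), seed = NULL) {
  if (!length(holdout)) {
    message("no holdout statistics configured: nothing to check")
    return(invisible(NULL))
  }
  maybeSeed(seed)
  rows <- which(ref@scenario == scenario)
  useStats <- setdiff(summaryStatNames(), holdout)
  z <- standardizeStats(ref@stats[rows, , drop = FALSE], useStats,
                        observed)
  d <- sqrt(rowSums(sweep(z$ref, 2, as.numeric(z$extra))^2))
  k <- min(nRetain, length(rows))
  sel <- order(d)[seq_len(k)]
  dmax <- max(d[sel])
  w <- 1 - (d[sel] / (dmax * (1 + 1e-12)))^2
  w[w <= 0] <- min(w[w > 0])
  de <- ref@design
  geomQ <- geomParamFromVar(de$varMultiStep)
  modelInt <- if (de$msatModel == "SMM") 0L else 1L
  spec <- NULL
  for (s in ref@specs) if (s@scenario == scenario) spec <- s
  simStats <- matrix(NA_real_, nSim, 18,
                     dimnames = list(NULL, summaryStatNames()))
  pick <- sample(sel, nSim, replace = TRUE, prob = w)
  for (i in seq_len(nSim)) {
    pv <- ref@params[rows[pick[i]], ]
    muL <- pmin(pmax(rgamma(de$L, shape = 2,
                            scale = pv["muMsatMean"] / 2), 1e-8), 1e-2)
    simStats[i, ] <- .cppSimulateScenario(pv["NATL"], pv["NMED"],
      pv["NbATL"], pv["NbMED"], pv["t"], pv["t1"], pv["Nanc"], muL,
      pv["muMt"], de$nATL, de$nMED, de$mtATL, de$mtMED, de$seqLen,
      de$tsRatio, modelInt, de$pStep, geomQ, FALSE)$stats
  }
  ppp <- vapply(holdout, function(s) {
    sims <- simStats[, s]
    sims <- sims[is.finite(sims)]
    if (!length(sims) || !is.finite(observed[s])) return(NA_real_)
    mean(sims <= observed[s])
  }, 0)
  zAll <- standardizeStats(simStats, summaryStatNames(), observed)
  ok <- complete.cases(zAll$ref)
  pc <- prcomp(zAll$ref[ok, , drop = FALSE], center = TRUE)
  pcaObs <- as.numeric(predict(pc, zAll$extra)[1, 1:2])
  list(ppp = ppp, pcaSim = pc$x[, 1:2], pcaObs = pcaObs)
}

#' Convert generations to years before present
#'
#' years = generations x generation time. The species' generation time of
#' 9 years converts the modal split time of 6690 generations to 60210
#' years before present.
#'
#' @param generations numeric vector of times in generations.
#' @param generationTime generation time in years (default 9).
#' @return years.
#' @export
generationsToYears <- function(generations, generationTime = 9) {
  generations * generationTime
}
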