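#' Fit the multi-environment mixed model by EM-REML
#'
#' Fits \eqn{y = X\beta + Z_g u_g + Z_{gl} u_{gl} + \epsilon} for one trait:
#' site as a fixed effect, genotype and genotype-by-site as random effects
#' (the interaction term is included only when two or more sites are
#' present).  Variance components are estimated by EM-REML on Henderson's
#' mixed-model equations - a derivative-free, robust scheme in which each
#' iteration solves the equations at the current variance ratios and
#' updates \eqn{\sigma^2_i = (\hat u_i'\hat u_i + \sigma^2_e\,
#' \mathrm{tr}\,C^{ii}) / q_i}.  Components are floored at zero; iteration
#' stops when the largest relative change drops below \code{tol}.
#'
#' @param table data.frame with columns \code{genotype}, \code{site},
#'   \code{rep} and trait columns; missing trait values are dropped.
#' @param trait trait column name.
#' @param R number of replications, stored for downstream heritability
#'   (an explicit input, never inferred from the data).
#' @param tol relative-change convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @return list with a \code{\linkS4class{VarianceComponents}} (\code{vc})
#'   and a \code{\linkS4class{BlupResult}} (\code{blup}).
#' @examples
#' tab <- simulateTraitTable(40, L = 2, R = 3, Vg = 4, Ve = 1, seed = 1)
#' fit <- fitMixedModel(tab, "y", R = 3)
#' fit$vc
#' @export
fitMixedModel <- function(table, trait, R, tol = 1e-8, maxIter = 1000L) {
  need <- c("genotype", "site", "rep", trait)
  if (!all(need %in% names(table)))
    stop("table must have columns genotype, site, rep and '", trait, "'")
  tab <- table[!is.na(table[[trait]]), , drop = FALSE]
  y <- tab[[trait]]
  g <- factor(tab$genotype)
  s <- factor(tab$site)
  G <- nlevels(g); L <- nlevels(s)
  if (G < 2) stop("need at least 2 genotypes")
  n <- length(y)
  useGL <- L >= 2

  X <- if (L == 1) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")) else
    stats::model.matrix(~s)
  p <- qr(X)$rank
  if (p < ncol(X)) stop("singular fixed-effect design")
  Zg <- stats::model.matrix(~g - 1)
  colnames(Zg) <- levels(g)
  if (useGL) {
    gl <- factor(paste(as.integer(g), as.integer(s), sep = ":"))
    Zgl <- stats::model.matrix(~gl - 1)
    GL <- ncol(Zgl)
  } else GL <- 0L

  XtX <- crossprod(X); XtZg <- crossprod(X, Zg)
  ZgtZg <- colSums(Zg^2)           # diagonal
  Xty <- crossprod(X, y); Zgty <- crossprod(Zg, y)
  if (useGL) {
    XtZgl <- crossprod(X, Zgl)
    ZgtZgl <- crossprod(Zg, Zgl)
    dGL <- colSums(Zgl^2)          # diagonal
    Zglty <- crossprod(Zgl, y)
  }
  yty <- sum(y^2)

  v <- stats::var(y)
  sg <- sgl <- se <- max(v / 3, 1e-8)
  if (!useGL) sgl <- 0
  iter <- 0L; converged <- FALSE
  floorV <- 1e-10
  prevTheta <- c(sg, sgl, se); prevDelta <- NULL

  # ridge for a component: a zeroed component is pinned by a huge ridge so
  # its effects vanish regardless of the residual scale; a tiny floor keeps
  # the equations well conditioned when the residual variance is ~0 (the
  # intercept/genotype confounding is otherwise resolved only at the limit)
  ridge <- function(s2) if (s2 <= 0) 1e12 else max(se / s2, 1e-8)
  repeat {
    iter <- iter + 1L
    k1 <- ridge(sg)
    A <- rbind(cbind(XtX, XtZg),
               cbind(t(XtZg), diag(ZgtZg + k1, G)))
    r1 <- c(Xty, Zgty)
    if (useGL) {
      k2 <- ridge(sgl)
      d <- dGL + k2
      B <- rbind(XtZgl, ZgtZgl)
      S <- A - B %*% (t(B) / d)
      rhs <- r1 - B %*% (Zglty / d)
      Sinv <- solve(S)
      th1 <- Sinv %*% rhs
      ugl <- (Zglty - t(B) %*% th1) / d
      Cgg <- Sinv[(p + 1):(p + G), (p + 1):(p + G)]
      Tm <- B / rep(d, each = nrow(B))
      trCglgl <- sum(1 / d) + sum(Tm * (Sinv %*% Tm))
    } else {
      Sinv <- solve(A)
      th1 <- Sinv %*% r1
      Cgg <- Sinv[(p + 1):(p + G), (p + 1):(p + G)]
    }
    beta <- th1[seq_len(p)]
    ug <- th1[(p + 1):(p + G)]

    ssr <- yty - sum(beta * Xty) - sum(ug * Zgty) -
      (if (useGL) sum(ugl * Zglty) else 0)
    seNew <- max(ssr / (n - p), floorV)
    sgNew <- max((sum(ug^2) + se * sum(diag(Cgg))) / G, 0)
    sglNew <- if (useGL)
      max((sum(ugl^2) + se * trCglgl) / GL, 0) else 0
    # a component creeping toward the boundary is absorbed to exactly 0
    # (EM approaches zero components only geometrically)
    tot <- sgNew + sglNew + seNew
    if (sgNew < 1e-7 * tot) sgNew <- 0
    if (sglNew < 1e-7 * tot) sglNew <- 0

    # relative to the total variance, so near-zero components cannot stall
    # convergence with numerically meaningless relative wobble
    delta <- max(abs(c(sgNew - sg, sglNew - sgl, seNew - se))) /
      max(sg + sgl + se, 1e-12)
    sg <- sgNew; sgl <- sglNew; se <- seNew
    if (delta < tol) { converged <- TRUE; break }
    # Aitken extrapolation along the (geometric) EM trajectory every few
    # iterations; accepted only when the contraction ratio is stable and
    # the jump stays in the parameter space
    theta <- c(sg, sgl, se)
    dNow <- theta - prevTheta
    if (!is.null(prevDelta) && iter %% 5L == 0L) {
      denom <- sum(prevDelta^2)
      if (denom > 0) {
        r <- sum(dNow * prevDelta) / denom
        if (r > 0.3 && r < 0.999) {
          cand <- theta + dNow * r / (1 - r)
          if (all(cand[c(1, 3)] >= 0) && cand[2] >= 0) {
            sg <- cand[1]; sgl <- if (useGL) cand[2] else 0; se <- max(cand[3], floorV)
            theta <- c(sg, sgl, se)
          }
        }
      }
    }
    prevDelta <- dNow; prevTheta <- theta
    if (iter >= maxIter) break
  }
  if (!converged)
    stop(sprintf("EM-REML did not converge in %d iterations (last Vg=%.6g, Vgl=%.6g, Ve=%.6g, rel. change %.3g)",
                 iter, sg, sgl, se, delta))

  grandMean <- mean(X %*% beta)
  blupDf <- data.frame(genotype = levels(g), u = as.numeric(ug),
                       blup = grandMean + as.numeric(ug))
  names(beta) <- colnames(X)
  vc <- new("VarianceComponents", Vg = max(sg, 0), Vgl = max(sgl, 0),
            Ve = max(se, 0), L = L, R = as.integer(R),
            iterations = iter, converged = converged)
  blup <- new("BlupResult", blup = blupDf, beta = beta,
              grandMean = grandMean, trait = trait)
  list(vc = vc, blup = blup)
}

#' Simulate a balanced multi-environment trait table
#'
#' Genotype effects ~ N(0, Vg), genotype-by-site effects ~ N(0, Vgl),
#' residuals ~ N(0, Ve); fixed site effects drawn once ~ N(0, 1).
#'
#' @param nGenotypes,L,R design dimensions.
#' @param Vg,Vgl,Ve variance components.
#' @param mu grand mean.
#' @param seed integer seed.
#' @return data.frame with columns \code{genotype}, \code{site}, \code{rep},
#'   \code{y}.
#' @export
simulateTraitTable <- function(nGenotypes, L, R, Vg, Vgl = 0, Ve,
                               mu = 10, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    siteEff <- stats::rnorm(L, 0, 1)
    u <- stats::rnorm(nGenotypes, 0, sqrt(Vg))
    ugl <- matrix(stats::rnorm(nGenotypes * L, 0, sqrt(Vgl)), nGenotypes, L)
    df <- expand.grid(rep = seq_len(R), site = seq_len(L),
                      genotype = seq_len(nGenotypes))
    df <- df[, c("genotype", "site", "rep")]
    df$y <- mu + siteEff[df$site] + u[df$genotype] +
      ugl[cbind(df$genotype, df$site)] +
      stats::rnorm(nrow(df), 0, sqrt(Ve))
  })
  df$genotype <- sprintf("G%03d", df$genotype)
  df$site <- sprintf("S%d", df$site)
  df
}

#' Broad-sense heritability
#'
#' \eqn{H^2 = V_g / (V_g + V_{gl}/L + V_e/(L R))} across \code{L} sites and
#' \code{R} replications.
#'
#' @param Vg genotypic variance, or a
#'   \code{\linkS4class{VarianceComponents}} object (then the remaining
#'   arguments are taken from it).
#' @param Vgl,Ve genotype-by-site and residual variances.
#' @param L,R site and replication counts.
#' @return H2 in [0, 1].
#' @examples
#' heritability(1, 1, 1, L = 2, R = 5)  # 0.625
#' @export
heritability <- function(Vg, Vgl, Ve, L, R) {
  if (is(Vg, "VarianceComponents")) {
    vc <- Vg; Vg <- vc@Vg; Vgl <- vc@Vgl; Ve <- vc@Ve; L <- vc@L; R <- vc@R
  }
  if (any(c(Vg, Vgl, Ve) < 0)) stop("variance components must be nonnegative")
  if (L < 1 || R < 1) stop("L and R must be >= 1")
  denom <- Vg + Vgl / L + Ve / (L * R)
  if (denom <= 0) stop("all variance components are zero: H2 undefined")
  Vg / denom
}

#' Phenotypic variance explained by one SNP
#'
#' \eqn{PVE = 2\beta^2 af(1-af) / (2\beta^2 af(1-af) + se^2\, 2N\, af(1-af))},
#' computed exactly in that form (the allele-frequency factors cancel
#' algebraically, so PVE = \eqn{\beta^2 / (\beta^2 + N\,se^2)}).
#'
#' @param beta allelic effect size.
#' @param se its standard error (> 0).
#' @param af minor allele frequency, strictly inside (0, 1).
#' @param N sample size (>= 2).
#' @return PVE in [0, 1); vectorized over its arguments.
#' @export
pve <- function(beta, se, af, N) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(af <= 0 | af >= 1)) stop("af must be in (0, 1): monomorphic SNP")
  if (any(N < 2)) stop("N must be >= 2")
  num <- 2 * beta^2 * af * (1 - af)
  num / (num + se^2 * 2 * N * af * (1 - af))
}

#' Holm step-down multiple-testing adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
holmAdjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Spearman correlation matrix with Holm-adjusted p-values
#'
#' Pairwise-complete Spearman rank correlations (mid-ranks for ties) with
#' p-values from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}, Holm-adjusted over the
#' \eqn{k(k-1)/2} unique trait pairs.  Pairs involving a constant column
#' are reported as \code{NA}.
#'
#' @param table numeric data.frame or matrix, one row per genotype, one
#'   column per trait.
#' @return list of matrices \code{rho}, \code{p} and \code{pAdjusted}.
#' @export
spearmanMatrix <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 3) stop("need at least 3 genotypes")
  k <- ncol(m)
  rho <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(m[, i], m[, j])
    n <- sum(ok)
    r <- rho[i, j]
    if (!is.finite(r) || n < 3) next
    if (abs(r) >= 1) { p[i, j] <- p[j, i] <- 0; next }
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  ut <- upper.tri(p)
  padj <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  vals <- p[ut]
  adj <- rep(NA_real_, length(vals))
  adj[!is.na(vals)] <- holmAdjust(vals[!is.na(vals)])
  padj[ut] <- adj
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  list(rho = rho, p = p, pAdjusted = padj)
}

#' Subpopulation trait comparison
#'
#' One-way ANOVA across groups plus all pairwise Welch two-sample t tests
#' with Holm adjustment over the pair set.
#'
#' @param values numeric trait vector.
#' @param groups group labels (factor or character).
#' @return list with \code{F}, \code{p} (overall ANOVA) and a
#'   \code{pairwise} data.frame (\code{group1}, \code{group2}, \code{t},
#'   \code{p}, \code{pAdjusted}).
#' @export
subpopTests <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(as.character(groups[ok]))
  sizes <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("degenerate group (fewer than 2 members): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  an <- stats::anova(stats::lm(values ~ groups))
  pairs <- utils::combn(levels(groups), 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   t = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    tt <- stats::t.test(values[groups == pairs[1, i]],
                        values[groups == pairs[2, i]])
    pw$t[i] <- unname(tt$statistic); pw$p[i] <- tt$p.value
  }
  pw$pAdjusted <- holmAdjust(pw$p)
  list(F = an$`F value`[1], p = an$`Pr(>F)`[1], pairwise = pw)
}

#' Filter a genotype matrix by MAF and call rate
#'
#' Keeps SNPs with minor allele frequency strictly greater than
#' \code{mafMin} and call rate strictly greater than \code{callRateMin}.
#' MAF is computed from non-missing calls (codes 0/1/2 = minor-allele
#' dosage) and folded to at most 0.5.
#'
#' @param geno integer matrix, SNPs in rows, individuals in columns, codes
#'   0/1/2 with \code{NA} for missing.
#' @param mafMin,callRateMin strict lower bounds.
#' @return the filtered matrix; per-SNP \code{maf} and \code{callRate} for
#'   the retained SNPs are attached as attributes.
#' @export
filterGenotypes <- function(geno, mafMin = 0.05, callRateMin = 0.9) {
  if (!is.matrix(geno)) stop("geno must be a matrix")
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  st <- snpStats(geno)
  keep <- !is.na(st$maf) & st$maf > mafMin & st$callRate > callRateMin
  out <- geno[keep, , drop = FALSE]
  attr(out, "maf") <- st$maf[keep]
  attr(out, "callRate") <- st$callRate[keep]
  out
}

#' Per-SNP MAF and call rate
#'
#' @param geno genotype matrix as in \code{\link{filterGenotypes}}.
#' @return data.frame with columns \code{maf} (folded to <= 0.5; \code{NA}
#'   when all calls are missing) and \code{callRate}.
#' @export
snpStats <- function(geno) {
  callRate <- rowMeans(!is.na(geno))
  af <- rowMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[callRate == 0] <- NA_real_
  data.frame(maf = maf, callRate = callRate,
             row.names = rownames(geno))
}

#' Read a genotype matrix TSV
#'
#' First column: SNP id (e.g. \code{chr1.s_48334591}); remaining columns:
#' one per individual, codes 0/1/2, missing as \code{NA}.
#'
#' @param path TSV file.
#' @return integer matrix with SNP ids as row names.
#' @export
readGenotypeTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Suggestive genome-wide significance threshold
#'
#' The reciprocal of the effective number of independent tests.
#'
#' @param effectiveN effective number of tests (> 0).
#' @return the suggestive p-value threshold.
#' @examples
#' suggestiveThreshold(399313.86)  # 2.50e-6
#' @export
suggestiveThreshold <- function(effectiveN) {
  if (!is.numeric(effectiveN) || any(effectiveN <= 0))
    stop("effectiveN must be positive")
  1 / effectiveN
}
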