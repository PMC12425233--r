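# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the package internals.

# Matched-fraction X:AA ratio, written from the procedure definition:
# fractions above threshold, smallest fraction, top-k by sort, median ratio.
oracle_xaa_by_fraction <- function(x, a, t, neox = NULL) {
  frac <- function(v) sum(v > t) / length(v)
  fs <- c(frac(x), frac(a), if (!is.null(neox)) frac(neox))
  f <- min(fs)
  if (f == 0) return(NULL)
  topk <- function(v) {
    k <- max(1, floor(f * length(v) + 1e-9))
    sort(v, decreasing = TRUE)[seq_len(k)]
  }
  out <- c(X = median(topk(x)) / median(topk(a)))
  if (!is.null(neox)) out <- c(out, NeoX = median(topk(neox)) / median(topk(a)))
  out
}

# Yates chi-square via the closed-form 2x2 identity
# N (|ad - bc| - N/2)^2 / (r1 r2 c1 c2), with the excess clipped at zero.
oracle_yates <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  num <- max(abs(a * d - b * c) - n / 2, 0)
  chi2 <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Two-group NB fit at fixed dispersion by direct likelihood optimization
# (Nelder-Mead on the log-likelihood), with the observed information from
# a central finite-difference Hessian. sf are size factors.
oracle_nb_fit <- function(ya, yb, alpha, sfa = rep(1, length(ya)),
                          sfb = rep(1, length(yb))) {
  nll <- function(beta) {
    mua <- sfa * exp(beta[1])
    mub <- sfb * exp(beta[1] + beta[2])
    -sum(dnbinom(ya, mu = mua, size = 1 / alpha, log = TRUE)) -
      sum(dnbinom(yb, mu = mub, size = 1 / alpha, log = TRUE))
  }
  start <- c(log(mean(ya) + 0.5), log((mean(yb) + 0.5) / (mean(ya) + 0.5)))
  fit <- optim(start, nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  h <- 1e-4
  hess <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    e_i <- e_j <- c(0, 0); e_i[i] <- h; e_j[j] <- h
    hess[i, j] <- (nll(fit$par + e_i + e_j) - nll(fit$par + e_i - e_j) -
                     nll(fit$par - e_i + e_j) + nll(fit$par - e_i - e_j)) / (4 * h^2)
  }
  se <- sqrt(solve(hess)[2, 2])
  z <- fit$par[2] / se
  list(log2fc = fit$par[2] / log(2), se = se / log(2),
       p = 2 * pnorm(-abs(z)))
}

# Exhaustive-partition optimum of the k = 2 within-cluster sum of squares.
oracle_wcss_k2 <- function(pts) {
  n <- nrow(pts)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(grp) || all(grp)) next
    wcss <- 0
    for (g in list(grp, !grp)) {
      sub <- pts[g, , drop = FALSE]
      cen <- colMeans(sub)
      wcss <- wcss + sum(sweep(sub, 2, cen)^2)
    }
    best <- min(best, wcss)
  }
  best
}

# Rule-by-rule ortholog filter oracle: plain loops over tuples.
oracle_filter_orthologs <- function(tab, anns) {
  keep <- character(0)
  why <- list()
  for (oid in unique(tab$ortholog_id)) {
    members <- tab[tab$ortholog_id == oid, ]
    info <- do.call(rbind, lapply(seq_len(nrow(members)), function(i) {
      a <- anns[[members$species[i]]]
      a[a$gene_id == members$gene_id[i],
        c("muller_element", "chromosome_class", "n_transcripts")]
    }))
    if (any(info$n_transcripts != 1)) {
      why[[oid]] <- 1L
    } else if (length(unique(info$muller_element)) > 1) {
      why[[oid]] <- 2L
    } else if (any(info$chromosome_class == "Y") || any(info$muller_element == "D")) {
      why[[oid]] <- 3L
    } else {
      keep <- c(keep, oid)
    }
  }
  list(retained = keep, criterion = unlist(why))
}

# Small default simulation shared by tests that only need structure.
tiny_sim <- function(seed = 42, ...) {
  simulate_experiment(simulation_config(
    seed = seed, n_genes = c(X = 60, Autosome = 240, Dot = 10, Y = 5), ...))
}
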