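# Internal adaptive random-walk Metropolis-within-Gibbs sampler.
#
# Parameters live on unconstrained (log / logit) scales; the caller's
# log-posterior closure is responsible for transforms, Jacobians and any
# caching of expensive intermediates. Blocks are updated in turn with
# multivariate normal proposals whose per-coordinate scales adapt to the
# running sample variance during burn-in, and whose global step size is
# tuned by Robbins-Monro towards an acceptance rate of 0.234 for
# multivariate blocks and 0.44 for scalars. Adaptation is frozen after
# burn-in.

run_adaptive_mcmc <- function(log_post, init, blocks, n_burn, n_save,
                              thin = 1, seed = NULL) {
  with_seed(seed, {
    par <- init
    np <- length(par)
    lp <- log_post(par)
    if (!is.finite(lp)) stop_invalid("initial state has zero posterior density")
    nb <- length(blocks)
    bsize <- lengths(blocks)
    scale <- ifelse(bsize == 1, 0.5, 2.38 / sqrt(bsize))
    # per-block running mean/covariance for Haario-style proposals; the
    # empirical covariance captures posterior ridges that per-coordinate
    # scaling cannot follow
    bmean <- lapply(blocks, function(b) par[b])
    bcov <- lapply(blocks, function(b) diag(0.01, length(b)))
    bchol <- lapply(blocks, function(b) diag(0.1, length(b)))
    n_adapt <- 0L
    acc <- rep(0, nb)
    tries <- rep(0, nb)
    total_iter <- n_burn + n_save * thin
    draws <- matrix(NA_real_, n_save, np,
                    dimnames = list(NULL, names(init)))
    isave <- 0L
    for (iter in seq_len(total_iter)) {
      adapting <- iter <= n_burn
      for (j in seq_len(nb)) {
        b <- blocks[[j]]
        p <- bsize[j]
        target <- if (p == 1) 0.44 else 0.234
        prop <- par
        step <- if (p == 1) {
          rnorm(1, 0, scale[j] * bchol[[j]][1, 1])
        } else {
          scale[j] * as.numeric(rnorm(p) %*% bchol[[j]])
        }
        prop[b] <- par[b] + step
        lp_new <- log_post(prop)
        tries[j] <- tries[j] + 1
        accept <- is.finite(lp_new) && (log(runif(1)) < lp_new - lp)
        if (accept) {
          par <- prop
          lp <- lp_new
          acc[j] <- acc[j] + 1
        }
        if (adapting) {
          rate <- if (accept) 1 else 0
          scale[j] <- scale[j] *
            exp((rate - target) / sqrt(1 + iter / 10))
        }
      }
      if (adapting) {
        n_adapt <- n_adapt + 1L
        w <- 1 / (n_adapt + 1)
        for (j in seq_len(nb)) {
          b <- blocks[[j]]
          d <- par[b] - bmean[[j]]
          bmean[[j]] <- bmean[[j]] + w * d
          bcov[[j]] <- (1 - w) * (bcov[[j]] + w * tcrossprod(d))
          if (n_adapt >= 50L && n_adapt %% 25L == 0L) {
            ch <- tryCatch(
              chol(bcov[[j]] + diag(1e-8, bsize[j])),
              error = function(e) NULL)
            if (!is.null(ch)) bchol[[j]] <- ch
          }
        }
      } else if ((iter - n_burn) %% thin == 0) {
        isave <- isave + 1L
        draws[isave, ] <- par
      }
    }
    list(draws = draws, acceptance = acc / pmax(tries, 1),
         final = par, log_post = lp)
  })
}

# Split-chain potential scale reduction factor (Gelman-Rubin R-hat).
split_rhat <- function(chain_list) {
  halves <- list()
  for (ch in chain_list) {
    n <- nrow(ch)
    h <- floor(n / 2)
    if (h < 2) return(rep(NA_real_, ncol(chain_list[[1]])))
    halves <- c(halves, list(ch[1:h, , drop = FALSE]),
                list(ch[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  vapply(seq_len(ncol(halves[[1]])), function(p) {
    means <- vapply(halves, function(h) mean(h[, p]), numeric(1))
    vars <- vapply(halves, function(h) var(h[, p]), numeric(1))
    W <- mean(vars)
    B <- n * var(means)
    if (W < 1e-12) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' MCMC configuration
#'
#' Sampler settings for [fit_state_space()] and [update_with_trends()].
#' The default is a scaled-down configuration (4 chains, 2000 burn-in,
#' 2000 saved draws per chain); `full_scale = TRUE` switches to the heavy
#' setting of 20 chains, 5000 burn-in and 10,000 total saved samples.
#'
#' @param n_chains Number of independent chains.
#' @param n_burn Burn-in iterations per chain (adaptation happens here).
#' @param n_save Saved draws per chain after burn-in.
#' @param thin Thinning interval.
#' @param rhat_threshold Convergence warning threshold for split R-hat.
#' @param full_scale If `TRUE`, override with the heavy configuration.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_burn = 2000, n_save = 2000,
                        thin = 1, rhat_threshold = 1.1,
                        full_scale = FALSE) {
  if (full_scale) {
    n_chains <- 20
    n_burn <- 5000
    n_save <- ceiling(10000 / n_chains)
  }
  structure(list(n_chains = n_chains, n_burn = n_burn, n_save = n_save,
                 thin = thin, rhat_threshold = rhat_threshold),
            class = "mcmc_config")
}

# Run multiple chains of the block sampler and assemble a posterior_draws
# object; `transform` maps a matrix of unconstrained draws to the natural
# scale.
run_chains <- function(log_post_factory, init_factory, blocks, mcmc, seed,
                       transform) {
  chains <- vector("list", mcmc$n_chains)
  accs <- vector("list", mcmc$n_chains)
  for (c in seq_len(mcmc$n_chains)) {
    lp <- log_post_factory()
    init <- init_factory(c)
    res <- run_adaptive_mcmc(lp, init, blocks, mcmc$n_burn, mcmc$n_save,
                             mcmc$thin, seed = derive_seed(seed, c))
    chains[[c]] <- res$draws
    accs[[c]] <- res$acceptance
  }
  rhat <- split_rhat(chains)
  names(rhat) <- colnames(chains[[1]])
  flagged <- any(rhat > mcmc$rhat_threshold, na.rm = TRUE)
  if (flagged) {
    warning(sprintf(
      "possible non-convergence: max split R-hat = %.3f (threshold %.2f)",
      max(rhat, na.rm = TRUE), mcmc$rhat_threshold))
  }
  raw <- do.call(rbind, chains)
  samples <- transform(raw)
  structure(list(samples = samples, raw = raw, chains = chains,
                 diagnostics = list(rhat = rhat,
                                    acceptance = do.call(rbind, accs),
                                    converged = !flagged),
                 config = mcmc),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d samples x %d parameters (%d chains)\n",
              nrow(x$samples), ncol(x$samples), length(x$chains)))
  cat(sprintf("  max split R-hat: %.3f (%s)\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              if (x$diagnostics$converged) "converged" else "flagged"))
  invisible(x)
}
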