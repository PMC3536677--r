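
# Dirichlet-process Gaussian mixture clustering of timecourse profiles -------
#
# Model: M(g,t,r) = mu_{k(g)}(t) + c_g + d_{g,t} + e_{g,t,r} with
# c_g ~ N(0, sc2), d_{g,t} ~ N(0, st2), e ~ N(0, sr2), and a Dirichlet-process
# prior (concentration alpha) on the partition k.  Conditional on the cluster
# mean, c and d are marginalized analytically: the per-time replicate means
# ybar_{g,t} have compound-symmetric covariance lam_b I + sc2 J with
# lam_b = st2 + sr2/R, whose eigenstructure (ones direction lam_b + T*sc2,
# contrasts lam_b) gives a closed-form likelihood.  Because the N(0, tau2 I)
# prior on cluster means is conjugate to that likelihood, allocations are
# sampled by collapsed CRP Gibbs (cluster means integrated out; the
# posterior-predictive covariance of a member profile is again of the form
# a*I + b*J, so every weight is closed-form).  Cluster means are then
# re-instantiated by conjugate draws each sweep, and the variance components
# move by random-walk Metropolis on the log scale.

#' Prior expected number of clusters under a Dirichlet process
#'
#' The Chinese-restaurant-process closed form: `E[K] = sum_{i=0}^{n-1}
#' alpha / (alpha + i)`.
#'
#' @param alpha Concentration parameter (> 0).
#' @param n Number of items (>= 1).
#' @return Expected number of occupied clusters.
#' @export
dp_expected_k <- function(alpha, n) {
  assert_that(alpha > 0, "alpha must be positive")
  assert_that(n >= 1, "n must be at least 1")
  sum(alpha / (alpha + seq_len(n) - 1))
}

# log N(y; centre column, a*I + b*J) for compound-symmetric covariance,
# vectorized over candidate centres (columns) with per-column a, b
profile_loglik <- function(ybar_g, centre_mat, a, b, T_) {
  u <- centre_mat - ybar_g        # sign irrelevant for the quadratic form
  ubar <- colMeans(u)
  ssdev <- colSums(u^2) - T_ * ubar^2
  lam1 <- a + T_ * b
  -0.5 * ((T_ - 1) * log(2 * pi * a) + log(2 * pi * lam1)) -
    ssdev / (2 * a) - T_ * ubar^2 / (2 * lam1)
}

#' Fit a Dirichlet-process mixture to replicated timecourse profiles
#'
#' Runs the MCMC described above and returns post-burn-in samples of the
#' allocation vector, occupied-cluster count, cluster mean profiles, variance
#' components and (optionally resampled) concentration parameter.  Results
#' are deterministic given `seed`.
#'
#' @param profiles Tibble `transcript_id, time, rep, M` on a complete
#'   (time, rep) grid shared by all transcripts.  A median-collapsed input
#'   (one "replicate") is accepted; the replicate component is then absorbed
#'   into the time-deviation component.
#' @param n_sweeps,burn_in Total Gibbs sweeps and discarded initial sweeps.
#' @param seed Integer seed (mandatory; the sampler is stochastic).
#' @param alpha DP concentration parameter.
#' @param resample_alpha If `TRUE`, resample alpha under a Gamma(1,1) prior
#'   (auxiliary-variable method).
#' @param tau2 Prior variance of cluster mean profiles (mean-zero normal).
#' @param sigma_init Named initial values for `sc`, `st`, `sr` (SDs).
#' @param update_variances If `FALSE`, variance components stay fixed at
#'   `sigma_init` (useful for oracle checks).
#' @param prior_only If `TRUE`, the likelihood is disabled and allocations are
#'   sampled from the CRP prior alone (used to validate the sampler against
#'   the closed-form prior expectation).
#' @param proposal_sd Random-walk SD on the log-variance scale.
#' @return A `dp_fit` object: list with `z_samples` (samples x transcripts),
#'   `K`, `mu_samples`, `sig2_samples`, `alpha_samples`, `transcript_ids`,
#'   `times`, `n_reps`, acceptance diagnostics.
#' @export
dp_fit <- function(profiles, n_sweeps = 2000, burn_in = 500, seed = 1,
                   alpha = 1, resample_alpha = FALSE, tau2 = 4,
                   sigma_init = c(sc = 0.15, st = 0.1, sr = 0.2),
                   update_variances = TRUE, prior_only = FALSE,
                   proposal_sd = 0.3) {
  assert_cols(profiles, c("transcript_id", "time", "rep", "M"), "profiles")
  assert_that(n_sweeps > burn_in, "n_sweeps must exceed burn_in")
  assert_that(nrow(profiles) > 0, "profiles must be non-empty")
  set.seed(as.integer(seed))

  profiles <- arrange(profiles, .data$transcript_id, .data$time, .data$rep)
  ids <- unique(profiles$transcript_id)
  times <- sort(unique(profiles$time))
  reps <- sort(unique(profiles$rep))
  n <- length(ids); T_ <- length(times); R_ <- length(reps)
  assert_that(nrow(profiles) == n * T_ * R_,
              "profiles must cover a complete transcript x time x rep grid")
  assert_that(!anyNA(profiles$M), "profiles must not contain missing M values")

  Y <- array(profiles$M, dim = c(R_, T_, n))        # rep fastest, then time
  ybar <- t(apply(Y, 3, colMeans))                  # n x T (rowMeans over reps)
  if (R_ == 1) ybar <- matrix(Y[1, , ], nrow = n, byrow = TRUE)
  ssw <- sum((aperm(Y, c(3, 2, 1)) - array(ybar, dim = c(n, T_, R_)))^2)

  sc2 <- unname(sigma_init[["sc"]]^2)
  st2 <- unname(sigma_init[["st"]]^2)
  sr2 <- unname(sigma_init[["sr"]]^2)

  # state: z labels, sizes, S = T x K matrix of member ybar sums, mu: T x K
  z <- seq_len(n)                      # singleton initialization
  sizes <- rep(1L, n)
  S <- t(ybar)
  mu <- S

  n_keep <- n_sweeps - burn_in
  z_samples <- matrix(NA_integer_, n_keep, n)
  K_samples <- integer(n_keep)
  mu_samples <- vector("list", n_keep)
  sig2_samples <- matrix(NA_real_, n_keep, 3,
                         dimnames = list(NULL, c("sc2", "st2", "sr2")))
  alpha_samples <- numeric(n_keep)
  acc <- c(sc2 = 0, st2 = 0, sr2 = 0); n_prop <- 0; n_divergent <- 0

  full_loglik <- function(sc2, st2, sr2) {
    if (any(c(sc2, st2, sr2) <= 0)) return(-Inf)
    lam_b <- st2 + sr2 / R_
    lam_1 <- lam_b + T_ * sc2
    U <- ybar - t(mu[, z, drop = FALSE])
    ub <- rowMeans(U)
    ssd <- rowSums(U^2) - T_ * ub^2
    tm <- sum(-0.5 * ((T_ - 1) * log(2 * pi * lam_b) + log(2 * pi * lam_1)) -
                ssd / (2 * lam_b) - T_ * ub^2 / (2 * lam_1))
    wn <- -0.5 * n * T_ * (R_ - 1) * log(2 * pi * sr2) - ssw / (2 * sr2)
    tm + wn
  }
  log_ig_prior <- function(v, a0 = 1, b0 = 0.5) -(a0 + 1) * log(v) - b0 / v

  for (sweep in seq_len(n_sweeps)) {
    lam_b <- st2 + sr2 / R_
    lam_1 <- lam_b + T_ * sc2

    ## -- allocations (collapsed CRP Gibbs; cluster means integrated out) ----
    for (g in seq_len(n)) {
      k_old <- z[g]
      sizes[k_old] <- sizes[k_old] - 1L
      S[, k_old] <- S[, k_old] - ybar[g, ]
      if (sizes[k_old] == 0L) {
        keep <- setdiff(seq_along(sizes), k_old)
        sizes <- sizes[keep]
        S <- S[, keep, drop = FALSE]
        z <- ifelse(z > k_old, z - 1L, z)
        z[g] <- NA_integer_
      }
      K <- length(sizes)
      if (prior_only) {
        logw <- c(log(sizes), log(alpha))
      } else {
        # posterior of mu_k given members: cov c*I + d*J, mean from S_k
        A <- sizes / lam_b + 1 / tau2
        B <- -sizes * sc2 / (lam_b * lam_1)
        cc <- 1 / A
        dd <- -B / (A * (A + T_ * B))
        colsum_S <- colSums(S)
        rhs <- S / lam_b - matrix(sc2 / (lam_b * lam_1) * colsum_S,
                                  T_, K, byrow = TRUE)
        mu_post <- rhs * matrix(cc, T_, K, byrow = TRUE) +
          matrix(dd * colSums(rhs), T_, K, byrow = TRUE)
        # predictive covariance = member cov + posterior-mean cov
        a_pred <- c(lam_b + cc, lam_b + tau2)
        b_pred <- c(sc2 + dd, sc2)
        centres <- cbind(mu_post, 0)
        logw <- c(log(sizes), log(alpha)) +
          profile_loglik(ybar[g, ], centres, a_pred, b_pred, T_)
      }
      logw <- logw - max(logw)
      pick <- sample.int(K + 1, 1, prob = exp(logw))
      if (pick <= K) {
        z[g] <- pick
        sizes[pick] <- sizes[pick] + 1L
        S[, pick] <- S[, pick] + ybar[g, ]
      } else {
        sizes <- c(sizes, 1L)
        S <- cbind(S, ybar[g, ])
        z[g] <- length(sizes)
      }
    }

    ## -- cluster means (conjugate draws, compound-symmetric closed form) ----
    mu <- matrix(0, T_, length(sizes))
    for (k in seq_along(sizes)) {
      nk <- sizes[k]
      A <- nk / lam_b + 1 / tau2
      B <- -nk * sc2 / (lam_b * lam_1)
      cc <- 1 / A
      rhs <- S[, k] / lam_b - (sc2 / (lam_b * lam_1)) * sum(S[, k])
      mean_post <- cc * rhs - (B / (A * (A + T_ * B))) * sum(rhs)
      zt <- rnorm(T_)
      mu[, k] <- mean_post + sqrt(cc) * (zt - mean(zt)) +
        rnorm(1, 0, sqrt(1 / (T_ * (A + T_ * B))))
    }

    ## -- variance components (log-scale random walk) ------------------------
    if (update_variances && !prior_only) {
      cur_ll <- full_loglik(sc2, st2, sr2)
      for (which_v in 1:3) {
        v <- c(sc2, st2, sr2)
        prop <- v
        prop[which_v] <- exp(log(v[which_v]) + rnorm(1, 0, proposal_sd))
        new_ll <- full_loglik(prop[1], prop[2], prop[3])
        n_prop <- n_prop + 1
        if (!is.finite(new_ll)) { n_divergent <- n_divergent + 1; next }
        logr <- new_ll - cur_ll +
          log_ig_prior(prop[which_v]) - log_ig_prior(v[which_v]) +
          log(prop[which_v]) - log(v[which_v])
        if (log(runif(1)) < logr) {
          sc2 <- prop[1]; st2 <- prop[2]; sr2 <- prop[3]
          cur_ll <- new_ll
          acc[which_v] <- acc[which_v] + 1
        }
      }
    }

    ## -- concentration parameter -------------------------------------------
    if (resample_alpha) {
      K <- length(sizes)
      eta <- rbeta(1, alpha + 1, n)
      odds <- (1 + K - 1) / (n * (1 - log(eta)))
      pi_mix <- odds / (1 + odds)
      alpha <- if (runif(1) < pi_mix) {
        rgamma(1, 1 + K, 1 - log(eta))
      } else {
        rgamma(1, 1 + K - 1, 1 - log(eta))
      }
    }

    if (sweep > burn_in) {
      i <- sweep - burn_in
      z_samples[i, ] <- z
      K_samples[i] <- length(sizes)
      mu_samples[[i]] <- mu
      sig2_samples[i, ] <- c(sc2, st2, sr2)
      alpha_samples[i] <- alpha
    }
  }

  if (n_prop > 0 && n_divergent / n_prop > 0.2) {
    warn(sprintf("%.0f%% of variance proposals were divergent",
                 100 * n_divergent / n_prop))
  }

  structure(
    list(
      z_samples = z_samples, K = K_samples, mu_samples = mu_samples,
      sig2_samples = sig2_samples, alpha_samples = alpha_samples,
      transcript_ids = ids, times = times, n_reps = R_,
      n_sweeps = n_sweeps, burn_in = burn_in,
      accept_rate = if (n_prop > 0) acc / (n_prop / 3) else acc,
      divergent_rate = if (n_prop > 0) n_divergent / n_prop else 0
    ),
    class = "dp_fit"
  )
}

#' @export
print.dp_fit <- function(x, ...) {
  cat("<dp_fit> ", length(x$transcript_ids), " transcripts, ",
      nrow(x$z_samples), " retained samples, modal K = ",
      modal_value(x$K), "\n", sep = "")
  invisible(x)
}

modal_value <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Summarize a Dirichlet-process fit into relabeled cluster assignments
#'
#' Label switching makes raw allocation samples incomparable across sweeps.
#' The summary (i) computes the pairwise co-clustering probability matrix,
#' (ii) takes as reference the sampled partition minimizing the least-squares
#' distance to that matrix, (iii) relabels every sample against the reference
#' by greedy maximum-overlap matching, and (iv) reports, per transcript, the
#' primary and secondary cluster with their allocation probabilities, plus
#' relabeled mean profiles and the posterior modal cluster count.
#'
#' @param fit A [dp_fit()] object with at least 100 retained samples.
#' @return A `dp_summary` object: list with `K` (posterior modal occupied
#'   count), `assignments` tibble, `profiles` tibble (`cluster, time, mu`),
#'   `coclust` matrix, and `K_table`.
#' @export
dp_summarize <- function(fit) {
  stopifnot(inherits(fit, "dp_fit"))
  S <- nrow(fit$z_samples)
  assert_that(S >= 100, "need at least 100 post-burn-in samples")
  n <- ncol(fit$z_samples)

  P <- matrix(0, n, n)
  for (s in seq_len(S)) {
    zs <- fit$z_samples[s, ]
    for (k in unique(zs)) {
      idx <- which(zs == k)
      P[idx, idx] <- P[idx, idx] + 1
    }
  }
  P <- P / S

  # least-squares reference partition (Dahl): minimize sum over same-cluster
  # pairs of (1 - 2 P_ij), a monotone transform of ||delta - P||^2
  ls_cost <- vapply(seq_len(S), function(s) {
    zs <- fit$z_samples[s, ]
    tot <- 0
    for (k in unique(zs)) {
      idx <- which(zs == k)
      tot <- tot + sum(1 - 2 * P[idx, idx])
    }
    tot
  }, numeric(1))
  ref <- fit$z_samples[which.min(ls_cost), ]
  ref_labels <- unique(ref)
  K_ref <- length(ref_labels)
  ref_z <- match(ref, ref_labels)

  K_max <- max(fit$K, K_ref)
  alloc <- matrix(0, n, K_max + 5)
  mu_sum <- matrix(0, length(fit$times), ncol(alloc))
  mu_cnt <- numeric(ncol(alloc))

  for (s in seq_len(S)) {
    zs <- fit$z_samples[s, ]
    labs <- sort(unique(zs))
    O <- matrix(0, length(labs), K_ref)
    for (i in seq_along(labs)) {
      members <- which(zs == labs[i])
      O[i, ] <- tabulate(ref_z[members], nbins = K_ref)
    }
    mapping <- integer(length(labs))
    Ow <- O
    next_new <- K_ref
    for (step in seq_along(labs)) {
      best <- which(Ow == max(Ow), arr.ind = TRUE)[1, , drop = TRUE]
      if (Ow[best[1], best[2]] > 0) {
        mapping[best[1]] <- best[2]
        Ow[best[1], ] <- -1
        Ow[, best[2]] <- -1
      }
    }
    for (i in seq_along(labs)) {
      if (mapping[i] == 0) {           # cluster with no reference overlap left
        next_new <- next_new + 1
        mapping[i] <- min(next_new, ncol(alloc))
      }
    }
    z_rel <- mapping[match(zs, labs)]
    alloc[cbind(seq_len(n), z_rel)] <- alloc[cbind(seq_len(n), z_rel)] + 1
    mus <- fit$mu_samples[[s]]
    for (i in seq_along(labs)) {
      tgt <- mapping[i]
      mu_sum[, tgt] <- mu_sum[, tgt] + mus[, labs[i]]
      mu_cnt[tgt] <- mu_cnt[tgt] + 1
    }
  }

  prob <- alloc / S
  primary <- apply(prob, 1, which.max)
  primary_prob <- prob[cbind(seq_len(n), primary)]
  secondary <- apply(prob, 1, function(p) {
    p[which.max(p)] <- -Inf
    which.max(p)
  })
  secondary_prob <- prob[cbind(seq_len(n), secondary)]

  used <- which(mu_cnt > 0)
  profiles <- purrr::map(used, function(k) {
    tibble(cluster = k, time = fit$times, mu = mu_sum[, k] / mu_cnt[k])
  }) %>% bind_rows()

  structure(
    list(
      K = modal_value(fit$K),
      K_table = table(fit$K),
      assignments = tibble(
        transcript_id = fit$transcript_ids,
        primary = as.integer(primary),
        primary_prob = primary_prob,
        secondary = as.integer(secondary),
        secondary_prob = secondary_prob
      ),
      profiles = profiles,
      coclust = P,
      reference = tibble(transcript_id = fit$transcript_ids,
                         cluster = ref_z)
    ),
    class = "dp_summary"
  )
}

#' @export
print.dp_summary <- function(x, ...) {
  cat("<dp_summary> posterior modal K = ", x$K, "; ",
      nrow(x$assignments), " transcripts\n", sep = "")
  invisible(x)
}

#' Maximum a posteriori allocation from a summary
#'
#' @param summary A `dp_summary`.
#' @return Integer vector of primary cluster labels named by transcript.
#' @export
dp_map_allocation <- function(summary) {
  stopifnot(inherits(summary, "dp_summary"))
  setNames(summary$assignments$primary, summary$assignments$transcript_id)
}

#' @export
tidy.dp_fit <- function(x, ...) {
  tibble(
    sweep = seq_len(nrow(x$z_samples)) + x$burn_in,
    K = x$K,
    sc2 = x$sig2_samples[, "sc2"],
    st2 = x$sig2_samples[, "st2"],
    sr2 = x$sig2_samples[, "sr2"],
    alpha = x$alpha_samples
  )
}

#' @export
glance.dp_fit <- function(x, ...) {
  tibble(
    n_transcripts = length(x$transcript_ids),
    n_sweeps = x$n_sweeps,
    burn_in = x$burn_in,
    modal_K = modal_value(x$K),
    mean_K = mean(x$K),
    divergent_rate = x$divergent_rate
  )
}

#' @export
tidy.dp_summary <- function(x, ...) x$assignments

#' @export
glance.dp_summary <- function(x, ...) {
  tibble(K = x$K, n_transcripts = nrow(x$assignments),
         mean_primary_prob = mean(x$assignments$primary_prob))
}

#' @export
autoplot.dp_summary <- function(object, ...) {
  ggplot2::ggplot(object$profiles,
                  ggplot2::aes(x = .data$time, y = .data$mu,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "mean M (log2)",
                  colour = "cluster",
                  title = "Posterior mean cluster profiles") +
    ggplot2::theme_minimal()
}
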