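#' Spot size factors
#'
#' Sequencing-depth normalizers: each spot's total count divided by the
#' median spot total across all analyzed spots. All-zero spots are excluded
#' with a warning.
#'
#' @param counts Either a [taxa_matrix()] (columns = spots) or a long tibble
#'   with columns `section_id`, `barcode`, `count`.
#' @return Tibble `section_id` (if available), `barcode`, `total`, `s`.
#' @export
compute_size_factors <- function(counts) {
  if (is.matrix(counts)) {
    totals <- tibble(section_id = NA_character_,
                     barcode = colnames(counts),
                     total = as.numeric(colSums(counts)))
  } else {
    totals <- dplyr::summarise(dplyr::group_by(as_tibble(counts),
                                               .data$section_id, .data$barcode),
                               total = sum(.data$count), .groups = "drop")
  }
  zero <- totals$total == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero spot(s) excluded from size factors")
    totals <- totals[!zero, ]
  }
  if (!nrow(totals)) stop("no spot with nonzero total")
  totals$s <- totals$total / median(totals$total)
  totals
}

#' Rook adjacency of annotated grid spots
#'
#' Four-nearest-neighbour adjacency (grid distance 1 along x or y) restricted
#' to the given spots. Isolated spots are allowed and get a zero
#' neighbour count.
#'
#' @param x,y Integer grid coordinates of the spots.
#' @return List with sparse symmetric `W` (zero diagonal) and `K` (integer
#'   vector of neighbour counts).
#' @export
build_adjacency <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  key <- paste(x, y)
  idx <- setNames(seq_len(n), key)
  nbr_keys <- cbind(paste(x + 1L, y), paste(x - 1L, y),
                    paste(x, y + 1L), paste(x, y - 1L))
  ii <- integer(0); jj <- integer(0)
  for (d in 1:4) {
    j <- idx[nbr_keys[, d]]
    hit <- !is.na(j)
    ii <- c(ii, which(hit)); jj <- c(jj, unname(j[hit]))
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  W <- (W + Matrix::t(W)) / 2        # symmetrize (each edge found twice)
  W@x[] <- 1
  K <- as.integer(Matrix::rowSums(W))
  list(W = W, K = K)
}

#' Zero-inflated Poisson log-probability
#'
#' `log P(y)` under a Poisson(rate) gated by a Bernoulli dropout: zeros arise
#' with probability `theta` plus `(1 - theta) * exp(-rate)`; positive counts
#' with probability `(1 - theta)` times the Poisson mass.
#'
#' @param y Nonnegative integer counts.
#' @param rate Poisson rate(s), > 0.
#' @param theta Dropout probability in \[0, 1\].
#' @return Log-probabilities, vectorized over inputs.
#' @export
zip_logpmf <- function(y, rate, theta) {
  if (any(y < 0)) stop("y must be nonnegative")
  stopifnot(all(rate > 0), all(theta >= 0), all(theta <= 1))
  n <- max(length(y), length(rate), length(theta))
  y <- rep_len(y, n); rate <- rep_len(rate, n); theta <- rep_len(theta, n)
  out <- numeric(n)
  z <- y == 0
  out[z] <- log(theta[z] + (1 - theta[z]) * exp(-rate[z]))
  out[!z] <- log1p(-theta[!z]) + stats::dpois(y[!z], rate[!z], log = TRUE)
  out
}

#' CAR precision matrix
#'
#' The conditional autoregressive prior's precision `Q = tau * (K - alpha W)`
#' (equivalently `tau K (I - alpha K^{-1} W)`), symmetric and positive
#' definite for `alpha` in (0, 1) on connected components. Isolated spots
#' (zero neighbours) would make Q singular; with
#' `regularize_isolated = TRUE` (default) they receive a unit diagonal entry,
#' i.e. an independent N(0, 1/tau) prior.
#'
#' @param K Neighbour counts (vector or diagonal matrix).
#' @param W Symmetric adjacency matrix with zero diagonal.
#' @param alpha Spatial autocorrelation in (0, 1).
#' @param tau Conditional precision > 0.
#' @param regularize_isolated Give isolated spots a proper independent prior.
#' @return Sparse symmetric precision matrix.
#' @export
car_precision <- function(K, W, alpha, tau, regularize_isolated = TRUE) {
  stopifnot(alpha > 0, alpha < 1, tau > 0)
  W <- methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix")
  if (!Matrix::isSymmetric(W)) stop("W must be symmetric")
  if (is.matrix(K)) K <- diag(K)
  K <- as.numeric(K)
  if (regularize_isolated) K[K == 0] <- 1
  tau * (Matrix::Diagonal(x = K) - alpha * W)
}

#' Splotch priors
#'
#' @param sigma_l1 Fixed level-1 characteristic-expression prior sd
#'   (default 2).
#' @param theta_shape Beta prior shape parameters of the dropout probability
#'   (default `c(1, 2)`).
#' @param sigma_eps_scale Half-normal scale of the spot-noise sd
#'   (default 0.3).
#' @param tau_shape,tau_rate Inverse-gamma parameters of the CAR precision
#'   (default 1, 1). The autocorrelation `alpha` is uniform on (0, 1) and the
#'   level-2 sd is half-normal(0, 1).
#' @return List of class `splotch_priors`.
#' @export
splotch_priors <- function(sigma_l1 = 2, theta_shape = c(1, 2),
                           sigma_eps_scale = 0.3, tau_shape = 1, tau_rate = 1) {
  structure(list(sigma_l1 = sigma_l1, theta_shape = theta_shape,
                 sigma_eps_scale = sigma_eps_scale,
                 tau_shape = tau_shape, tau_rate = tau_rate),
            class = "splotch_priors")
}

#' Assemble model input from counts, annotations and layout
#'
#' Builds the per-section design used by [fit_splotch()]: MROI one-hot
#' indices, rook adjacency with precomputed spectral decompositions for the
#' CAR log-determinant, global size factors, and the section -> (condition,
#' animal) mapping defining the beta hierarchy. The model is two-level when
#' any condition has more than one animal, one-level otherwise (override
#' with `levels`).
#'
#' @param counts Long tibble (`taxon`, `section_id`, `barcode`, `count`).
#' @param annotations Annotation tibble (`barcode`, `mroi`, `section_id`,
#'   `condition`, `animal_id`).
#' @param layout An [array_layout()] with the grid coordinates.
#' @param levels `"auto"`, `"one"` or `"two"`.
#' @param size_factors Optional precomputed size factors (tibble
#'   `section_id`, `barcode`, `s`); by default computed from the counts with
#'   [compute_size_factors()]. Supplying them matters when the counts cover
#'   only a few genes, where self-computed totals would feed the analyzed
#'   gene back into its own normalizer.
#' @return A `splotch_input` object.
#' @export
splotch_input <- function(counts, annotations, layout,
                          levels = c("auto", "one", "two"),
                          size_factors = NULL) {
  levels <- match.arg(levels)
  annotations <- validate_annotations(annotations, layout)
  counts <- as_tibble(counts)
  sf <- if (is.null(size_factors)) compute_size_factors(counts) else {
    sf0 <- as_tibble(size_factors)
    stopifnot(all(c("section_id", "barcode", "s") %in% names(sf0)))
    if (!("total" %in% names(sf0))) {
      tot <- dplyr::summarise(dplyr::group_by(counts, .data$section_id,
                                              .data$barcode),
                              total = sum(.data$count), .groups = "drop")
      sf0 <- dplyr::left_join(sf0, tot, by = c("section_id", "barcode"))
      sf0$total[is.na(sf0$total)] <- 0
    }
    sf0
  }
  key_ann <- paste(annotations$section_id, annotations$barcode)
  key_sf <- paste(sf$section_id, sf$barcode)
  keep <- key_ann %in% key_sf
  if (!all(keep)) annotations <- annotations[keep, ]
  xy <- as.data.frame(layout[, c("barcode", "x", "y")])
  mroi_levels <- sort(unique(annotations$mroi))
  sec_meta <- dplyr::distinct(annotations[, c("section_id", "condition", "animal_id")])
  if (anyDuplicated(sec_meta$section_id)) {
    stop("a section maps to more than one (condition, animal)")
  }
  l1_levels <- sort(unique(sec_meta$condition))
  pair_levels <- sort(unique(paste(sec_meta$condition, sec_meta$animal_id, sep = "||")))
  two_level <- switch(levels,
    two = TRUE, one = FALSE,
    auto = any(tapply(sec_meta$animal_id, sec_meta$condition,
                      function(a) length(unique(a))) > 1))
  sections <- list()
  for (sec in unique(annotations$section_id)) {
    ann <- annotations[annotations$section_id == sec, ]
    sxy <- merge(ann, xy, by = "barcode", sort = FALSE)
    adj <- build_adjacency(sxy$x, sxy$y)
    Ktil <- pmax(adj$K, 1L)
    # eigenvalues of Ktil^{-1/2} W Ktil^{-1/2} for the CAR log-determinant
    dinv <- 1 / sqrt(Ktil)
    M <- Matrix::Diagonal(x = dinv) %*% adj$W %*% Matrix::Diagonal(x = dinv)
    eigs <- eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values
    ssf <- sf[match(paste(sec, sxy$barcode), key_sf), ]
    sections[[sec]] <- list(
      section_id = sec,
      barcode = sxy$barcode,
      mroi_idx = match(sxy$mroi, mroi_levels),
      W = adj$W, K = adj$K, Ktil = Ktil, eigs = eigs,
      logdetK = sum(log(Ktil)),
      s = ssf$s, total = ssf$total,
      l1 = match(ann$condition[1], l1_levels),
      pair = match(paste(ann$condition[1], ann$animal_id[1], sep = "||"),
                   pair_levels))
  }
  pair_l1 <- match(sub("\\|\\|.*$", "", pair_levels), l1_levels)
  structure(list(counts = counts, annotations = annotations,
                 sections = sections, mroi_levels = mroi_levels,
                 l1_levels = l1_levels, pair_levels = pair_levels,
                 pair_l1 = pair_l1, two_level = two_level,
                 taxa = sort(unique(counts$taxon))),
            class = "splotch_input")
}

#' @export
print.splotch_input <- function(x, ...) {
  cat("<splotch_input> ", length(x$taxa), " taxa, ", length(x$sections),
      " section(s), ", length(x$mroi_levels), " MROIs, ",
      if (x$two_level) "two-level" else "one-level", " hierarchy\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# HMC machinery (internal)

# model context for one taxon: flattened spot data + parameter layout
.splotch_ctx <- function(input, taxon, priors) {
  secs <- input$sections
  y <- s <- numeric(0); mroi <- pair <- sec_of <- integer(0)
  for (i in seq_along(secs)) {
    sc <- secs[[i]]
    cts <- input$counts[input$counts$taxon == taxon &
                          input$counts$section_id == sc$section_id, ]
    yk <- cts$count[match(sc$barcode, cts$barcode)]
    yk[is.na(yk)] <- 0L
    y <- c(y, yk); s <- c(s, sc$s)
    mroi <- c(mroi, sc$mroi_idx)
    pair <- c(pair, rep(sc$pair, length(yk)))
    sec_of <- c(sec_of, rep(i, length(yk)))
  }
  M <- length(input$mroi_levels)
  L1 <- length(input$l1_levels)
  P <- length(input$pair_levels)
  two <- input$two_level
  N <- length(y)
  # parameter layout in the unconstrained vector
  nb1 <- L1 * M
  nb2 <- if (two) P * M else 0L
  lay <- list(b1 = seq_len(nb1),
              b2 = if (two) nb1 + seq_len(nb2) else integer(0),
              lsig2 = if (two) nb1 + nb2 + 1L else integer(0),
              psi = nb1 + nb2 + two + seq_len(N),
              eps = nb1 + nb2 + two + N + seq_len(N))
  off <- nb1 + nb2 + two + 2L * N
  lay$ltheta <- off + 1L; lay$lalpha <- off + 2L
  lay$ltau <- off + 3L; lay$lsige <- off + 4L
  lay$npar <- off + 4L
  # per-spot column index into beta matrices
  cell <- if (two) (pair - 1L) * M + mroi else integer(0)
  l1_of_sec <- vapply(secs, `[[`, integer(1), "l1")
  cell1 <- (l1_of_sec[sec_of] - 1L) * M + mroi
  list(y = y, s = s, logs = log(s), mroi = mroi, cell = cell, cell1 = cell1,
       pair_l1 = input$pair_l1, sec_of = sec_of, secs = secs, N = N, M = M,
       L1 = L1, P = P, two = two, lay = lay, priors = priors,
       is_zero = y == 0, pos = y > 0,
       psi_split = split(seq_len(N), sec_of))
}

# Log posterior and gradient on the unconstrained scale.
#
# Sampling uses non-centered parameterizations to avoid hierarchical funnels:
#   beta2 = beta1[pair] + sigma_l2 * u2,  u2 ~ N(0, 1)
#   psi   = u_psi / sqrt(tau),            u_psi ~ N(0, (K - alpha W)^{-1})
#   eps   = sigma_eps * u_eps,            u_eps ~ N(0, 1)
# The natural-scale draws are reconstructed after sampling.
.splotch_lp_grad <- function(z, ctx) {
  lay <- ctx$lay; pr <- ctx$priors
  M <- ctx$M; two <- ctx$two
  b1 <- matrix(z[lay$b1], ctx$L1, M, byrow = TRUE)
  u_psi <- z[lay$psi]; u_eps <- z[lay$eps]
  theta <- stats::plogis(z[lay$ltheta])
  alpha <- stats::plogis(z[lay$lalpha])
  tau <- exp(z[lay$ltau])
  sige <- exp(z[lay$lsige])
  sqtau <- sqrt(tau)
  psi <- u_psi / sqtau
  eps <- sige * u_eps
  if (two) {
    u2 <- matrix(z[lay$b2], ctx$P, M, byrow = TRUE)
    sig2 <- exp(z[lay$lsig2])
    b2 <- b1[ctx$pair_l1, , drop = FALSE] + sig2 * u2
    B <- t(b2)[ctx$cell]
  } else {
    B <- t(b1)[ctx$cell1]
  }
  eta <- ctx$logs + B + psi + eps
  mu <- exp(eta)
  lp <- 0
  grad <- numeric(lay$npar)
  # --- ZIP likelihood
  z0 <- ctx$is_zero
  emu <- exp(-mu[z0])
  denom <- theta + (1 - theta) * emu
  lp <- lp + sum(log(denom)) +
    sum(log1p(-theta) + ctx$y[ctx$pos] * eta[ctx$pos] - mu[ctx$pos] -
          lgamma(ctx$y[ctx$pos] + 1))
  deta <- numeric(ctx$N)
  deta[z0] <- -(1 - theta) * emu * mu[z0] / denom
  deta[ctx$pos] <- ctx$y[ctx$pos] - mu[ctx$pos]
  dtheta <- sum((1 - emu) / denom) - sum(ctx$pos) / (1 - theta)
  # --- beta hierarchy
  s1 <- pr$sigma_l1
  lp <- lp - sum(b1^2) / (2 * s1^2)
  g_b1 <- -b1 / s1^2
  if (two) {
    lp <- lp - sum(u2^2) / 2
    # likelihood term accumulated per (pair, mroi) cell; `cell` is the linear
    # index into the M x P matrix t(b2)
    acc <- tapply(deta, ctx$cell, sum)
    lik_b2 <- matrix(0, M, ctx$P)
    lik_b2[as.integer(names(acc))] <- acc
    lik_b2 <- t(lik_b2)
    g_u2 <- sig2 * lik_b2 - u2
    g_b1 <- g_b1 + rowsum(lik_b2, ctx$pair_l1, reorder = TRUE)
    # half-normal(0,1) prior on sig2 + jacobian
    lp <- lp - sig2^2 / 2 + z[lay$lsig2]
    g_lsig2 <- sig2 * sum(lik_b2 * u2) - sig2^2 + 1
  } else {
    acc <- tapply(deta, ctx$cell1, sum)
    lik_b1 <- matrix(0, M, ctx$L1)
    lik_b1[as.integer(names(acc))] <- acc
    g_b1 <- g_b1 + t(lik_b1)
  }
  # --- CAR prior on u_psi (per section, unit precision K - alpha W)
  g_upsi <- deta / sqtau
  dlogdet_alpha <- 0; quadW_sum <- 0
  for (i in seq_along(ctx$secs)) {
    sc <- ctx$secs[[i]]
    ix <- ctx$psi_split[[i]]
    pj <- u_psi[ix]
    Wp <- as.numeric(sc$W %*% pj)
    quadK <- sum(sc$Ktil * pj^2)
    quadW <- sum(pj * Wp)
    lp <- lp + 0.5 * (sc$logdetK + sum(log1p(-alpha * sc$eigs))) -
      0.5 * (quadK - alpha * quadW)
    g_upsi[ix] <- g_upsi[ix] - (sc$Ktil * pj - alpha * Wp)
    quadW_sum <- quadW_sum + quadW
    dlogdet_alpha <- dlogdet_alpha - 0.5 * sum(sc$eigs / (1 - alpha * sc$eigs))
  }
  # --- spot noise (standard-normal raw scale)
  lp <- lp - sum(u_eps^2) / 2
  g_ueps <- deta * sige - u_eps
  se_sc <- pr$sigma_eps_scale
  lp <- lp - sige^2 / (2 * se_sc^2) + z[lay$lsige]
  g_lsige <- sige * sum(deta * u_eps) - sige^2 / se_sc^2 + 1
  # --- theta prior Beta(a, b) + jacobian
  a <- pr$theta_shape[1]; b <- pr$theta_shape[2]
  lp <- lp + (a - 1) * log(theta) + (b - 1) * log1p(-theta) +
    log(theta) + log1p(-theta)
  dtheta <- dtheta + (a - 1) / theta - (b - 1) / (1 - theta)
  g_ltheta <- dtheta * theta * (1 - theta) + (1 - 2 * theta)
  # --- alpha prior U(0,1) + jacobian
  lp <- lp + log(alpha) + log1p(-alpha)
  g_lalpha <- (dlogdet_alpha + 0.5 * quadW_sum) * alpha * (1 - alpha) +
    (1 - 2 * alpha)
  # --- tau prior InvGamma(shape, rate) + jacobian; eta depends on tau
  # through psi = u_psi / sqrt(tau)
  lp <- lp - (pr$tau_shape + 1) * log(tau) - pr$tau_rate / tau + z[lay$ltau]
  g_ltau <- -0.5 * sum(deta * psi) -
    (pr$tau_shape + 1) + pr$tau_rate / tau + 1
  grad[lay$b1] <- as.numeric(t(g_b1))
  if (two) {
    grad[lay$b2] <- as.numeric(t(g_u2))
    grad[lay$lsig2] <- g_lsig2
  }
  grad[lay$psi] <- g_upsi
  grad[lay$eps] <- g_ueps
  grad[lay$ltheta] <- g_ltheta
  grad[lay$lalpha] <- g_lalpha
  grad[lay$ltau] <- g_ltau
  grad[lay$lsige] <- g_lsige
  list(lp = lp, grad = grad)
}

# one leapfrog trajectory; returns proposal and log accept prob
.hmc_step <- function(z, lg, eps_step, n_leap, minv, ctx) {
  p <- rnorm(length(z)) / sqrt(minv)
  h0 <- -lg$lp + 0.5 * sum(p^2 * minv)
  znew <- z; g <- lg$grad
  p <- p + 0.5 * eps_step * g
  for (l in seq_len(n_leap)) {
    znew <- znew + eps_step * (minv * p)
    # overflowing trajectories are rejected below; the NaN warnings they
    # raise inside the density are expected during step-size search
    lgn <- suppressWarnings(.splotch_lp_grad(znew, ctx))
    if (!is.finite(lgn$lp)) {
      return(list(z = z, lg = lg, accept = FALSE, log_a = -Inf, divergent = TRUE))
    }
    p <- p + (if (l < n_leap) eps_step else 0.5 * eps_step) * lgn$grad
  }
  h1 <- -lgn$lp + 0.5 * sum(p^2 * minv)
  log_a <- h0 - h1
  divergent <- !is.finite(log_a) || (h1 - h0) > 1000
  if (is.finite(log_a) && log(runif(1)) < log_a) {
    list(z = znew, lg = lgn, accept = TRUE, log_a = min(0, log_a),
         divergent = divergent)
  } else {
    list(z = z, lg = lg, accept = FALSE,
         log_a = if (is.finite(log_a)) min(0, log_a) else -Inf,
         divergent = divergent)
  }
}

# single HMC chain with Stan-style windowed adaptation
.hmc_chain <- function(ctx, iter, warmup, init_jitter = 1,
                       target_accept = 0.8, leap_range = c(10L, 24L)) {
  npar <- ctx$lay$npar
  z <- rnorm(npar, 0, 0.1) * init_jitter
  z[ctx$lay$ltheta] <- stats::qlogis(0.1) + rnorm(1, 0, 0.1)
  z[ctx$lay$lalpha] <- 0
  z[ctx$lay$ltau] <- 0
  z[ctx$lay$lsige] <- log(0.3)
  if (ctx$two) z[ctx$lay$lsig2] <- log(0.5)
  lg <- .splotch_lp_grad(z, ctx)
  minv <- rep(1, npar)
  # dual averaging state
  eps_step <- 0.01
  mu_da <- log(10 * eps_step); log_eps_bar <- log(eps_step)
  h_bar <- 0; gamma <- 0.05; t0 <- 10; kappa <- 0.75
  w1 <- max(5L, round(0.3 * warmup)); w2 <- max(5L, round(0.5 * warmup))
  w3 <- warmup - w1 - w2
  collect <- matrix(0, w2, npar)
  keep <- matrix(0, iter - warmup, npar)
  n_div <- 0L; n_acc <- 0L
  da_iter <- 0L
  for (it in seq_len(iter)) {
    n_leap <- sample.int(leap_range[2] - leap_range[1] + 1L, 1L) + leap_range[1] - 1L
    st <- .hmc_step(z, lg, eps_step, n_leap, minv, ctx)
    z <- st$z; lg <- st$lg
    if (st$divergent && it > warmup) n_div <- n_div + 1L
    if (st$accept && it > warmup) n_acc <- n_acc + 1L
    if (it <= warmup) {
      # dual averaging of the step size
      da_iter <- da_iter + 1L
      a_prob <- min(1, exp(st$log_a))
      h_bar <- (1 - 1 / (da_iter + t0)) * h_bar +
        (target_accept - a_prob) / (da_iter + t0)
      log_eps <- mu_da - sqrt(da_iter) / gamma * h_bar
      w <- da_iter^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps_step <- exp(log_eps)
      if (it > w1 && it <= w1 + w2) collect[it - w1, ] <- z
      if (it == w1 + w2) {
        v <- apply(collect, 2, stats::var)
        minv <- (v * w2 + 1e-3 * 5) / (w2 + 5)   # regularized variances
        # restart step-size adaptation for the new metric
        eps_step <- exp(log_eps_bar)
        mu_da <- log(10 * eps_step); h_bar <- 0; da_iter <- 0L
        log_eps_bar <- log(eps_step)
      }
      if (it == warmup) eps_step <- exp(log_eps_bar)
    } else {
      keep[it - warmup, ] <- z
    }
  }
  list(draws = keep, eps = eps_step,
       accept_rate = n_acc / (iter - warmup),
       divergent = n_div)
}

# split-Rhat over an iterations x chains matrix
.split_rhat <- function(x) {
  n <- nrow(x) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  mu <- colMeans(halves)
  v <- apply(halves, 2, stats::var)
  W <- mean(v)
  B <- n * stats::var(mu)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the hierarchical ZIP spatial model for one taxon or gene
#'
#' Counts are modeled as zero-inflated Poisson with rate
#' `s * exp(B + psi + eps)`: `B` is the MROI characteristic expression with a
#' one- or two-level (condition / animal) normal hierarchy, `psi` a CAR
#' Gaussian Markov random field over the 4-neighbour spot grid of each
#' section, and `eps` i.i.d. spot noise. Posterior draws come from a
#' Hamiltonian Monte Carlo sampler with dual-averaged step size and a
#' diagonal metric adapted during warmup; genes are fitted independently.
#'
#' @param input A [splotch_input()].
#' @param taxon Row label of the taxon/gene to fit.
#' @param priors A [splotch_priors()].
#' @param chains Number of independent chains (default 4).
#' @param iter Total iterations per chain (default 200).
#' @param warmup Warmup iterations per chain (default 100).
#' @param seed Integer seed (chains are seeded deterministically from it).
#' @return A `splotch_fit`: posterior draws, parameter names, per-parameter
#'   split-Rhat, per-spot posterior-mean rates `lambda_mean`, and metadata.
#'   Divergent transitions above 10% are flagged in `diagnostics`, not fatal.
#' @export
fit_splotch <- function(input, taxon, priors = splotch_priors(), chains = 4L,
                        iter = 200L, warmup = 100L, seed = 1L) {
  stopifnot(taxon %in% input$taxa, iter > warmup)
  ctx <- .splotch_ctx(input, taxon, priors)
  chain_fits <- vector("list", chains)
  for (ch in seq_len(chains)) {
    chain_fits[[ch]] <- withr::with_seed(seed + 1000L * (ch - 1L),
      .hmc_chain(ctx, iter, warmup))
  }
  draws <- array(0, dim = c(iter - warmup, chains, ctx$lay$npar))
  lay0 <- ctx$lay
  for (ch in seq_len(chains)) {
    d <- chain_fits[[ch]]$draws
    # reconstruct natural-scale parameters from the non-centered draws
    tau_d <- exp(d[, lay0$ltau])
    sige_d <- exp(d[, lay0$lsige])
    d[, lay0$psi] <- d[, lay0$psi] / sqrt(tau_d)
    d[, lay0$eps] <- d[, lay0$eps] * sige_d
    if (ctx$two) {
      sig2_d <- exp(d[, lay0$lsig2])
      M0 <- ctx$M
      for (p in seq_len(ctx$P)) {
        l1 <- ctx$pair_l1[p]
        cols2 <- lay0$b2[(p - 1L) * M0 + seq_len(M0)]
        cols1 <- lay0$b1[(l1 - 1L) * M0 + seq_len(M0)]
        d[, cols2] <- d[, cols1] + sig2_d * d[, cols2]
      }
    }
    draws[, ch, ] <- d
  }
  M <- ctx$M; lay <- ctx$lay
  par_names <- character(lay$npar)
  bn <- as.vector(t(outer(input$l1_levels, input$mroi_levels,
                          function(a, b) paste0("beta1[", a, ",", b, "]"))))
  par_names[lay$b1] <- bn
  if (ctx$two) {
    bn2 <- as.vector(t(outer(input$pair_levels, input$mroi_levels,
                             function(a, b) paste0("beta2[", a, ",", b, "]"))))
    par_names[lay$b2] <- bn2
    par_names[lay$lsig2] <- "log_sigma_l2"
  }
  par_names[lay$psi] <- paste0("psi[", seq_len(ctx$N), "]")
  par_names[lay$eps] <- paste0("eps[", seq_len(ctx$N), "]")
  par_names[c(lay$ltheta, lay$lalpha, lay$ltau, lay$lsige)] <-
    c("logit_theta", "logit_alpha", "log_tau", "log_sigma_eps")
  rhat <- vapply(seq_len(lay$npar), function(p) .split_rhat(draws[, , p]),
                 numeric(1))
  # posterior-mean rate per spot: mean over draws of exp(B + psi + eps)
  nk <- dim(draws)[1] * chains
  flat <- matrix(draws, nrow = nk, ncol = lay$npar)
  Bcols <- if (ctx$two) {
    t(matrix(flat[, lay$b2], nk)[, ctx$cell])
  } else {
    t(matrix(flat[, lay$b1], nk)[, ctx$cell1])
  }
  lam <- exp(Bcols + t(flat[, lay$psi]) + t(flat[, lay$eps]))
  lambda_mean <- rowMeans(lam)
  spots <- tibble(
    section_id = vapply(ctx$secs, `[[`, character(1), "section_id")[ctx$sec_of],
    barcode = unlist(lapply(ctx$secs, `[[`, "barcode"), use.names = FALSE),
    mroi = input$mroi_levels[ctx$mroi],
    y = ctx$y, s = ctx$s, total = unlist(lapply(ctx$secs, `[[`, "total")),
    lambda_mean = lambda_mean)
  divergent <- sum(vapply(chain_fits, `[[`, integer(1), "divergent"))
  n_sampling <- (iter - warmup) * chains
  structure(list(
    taxon = taxon, draws = draws, par_names = par_names, rhat = rhat,
    spots = spots, mroi_levels = input$mroi_levels,
    l1_levels = input$l1_levels, pair_levels = input$pair_levels,
    two_level = ctx$two, priors = priors, lay = ctx$lay,
    chains = chains, iter = iter, warmup = warmup, seed = seed,
    diagnostics = list(
      divergent = divergent,
      divergent_frac = divergent / n_sampling,
      divergence_flag = divergent / n_sampling > 0.1,
      accept_rate = mean(vapply(chain_fits, `[[`, numeric(1), "accept_rate")),
      step_sizes = vapply(chain_fits, `[[`, numeric(1), "eps"))),
    class = "splotch_fit")
}

#' @export
print.splotch_fit <- function(x, ...) {
  cat("<splotch_fit> taxon ", x$taxon, ": ", x$chains, " chains x ",
      x$iter - x$warmup, " draws, ", length(x$par_names), " parameters, ",
      "max Rhat ", round(max(x$rhat, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Extract posterior draws of a characteristic-expression cell
#'
#' @param fit A `splotch_fit`.
#' @param level `"l1"` (condition level) or `"l2"` (condition-animal level;
#'   two-level fits only).
#' @param group Level label (condition, or `"condition||animal"`).
#' @param mroi MROI tag.
#' @return Numeric vector of pooled posterior draws.
#' @export
beta_draws <- function(fit, group, mroi, level = c("l1", "l2")) {
  level <- match.arg(level)
  nm <- if (level == "l1") paste0("beta1[", group, ",", mroi, "]") else
    paste0("beta2[", group, ",", mroi, "]")
  p <- match(nm, fit$par_names)
  if (is.na(p)) stop("no such beta cell: ", nm)
  as.numeric(fit$draws[, , p])
}

#' @export
tidy.splotch_fit <- function(x, pars = NULL, ...) {
  idx <- seq_along(x$par_names)
  if (!is.null(pars)) idx <- idx[grepl(pars, x$par_names)]
  purrr::map_dfr(idx, function(p) {
    d <- as.numeric(x$draws[, , p])
    tibble(term = x$par_names[p], estimate = mean(d), std.error = sd(d),
           conf.low = unname(stats::quantile(d, 0.05)),
           conf.high = unname(stats::quantile(d, 0.95)),
           rhat = x$rhat[p])
  })
}

#' @export
glance.splotch_fit <- function(x, ...) {
  tibble(taxon = x$taxon, chains = x$chains,
         draws = (x$iter - x$warmup) * x$chains,
         max_rhat = max(x$rhat, na.rm = TRUE),
         accept_rate = x$diagnostics$accept_rate,
         divergent_frac = x$diagnostics$divergent_frac,
         two_level = x$two_level)
}

# ---------------------------------------------------------------------------
# Savage-Dickey Bayes factors and calls

#' Savage-Dickey Bayes factor from contrast draws
#'
#' `BF = p(delta = 0) / p(delta = 0 | data)`: the prior density of the
#' contrast at zero (closed form: difference of independent normals) over the
#' posterior density at zero, the latter from a normal approximation of the
#' draws (default) or a kernel density estimate.
#'
#' @param delta_draws Posterior draws of the contrast.
#' @param prior_sd Prior standard deviation of the contrast.
#' @param method `"normal"` (moment match, default) or `"kde"`.
#' @return One-row tibble: `delta_mean`, `delta_sd`, `bf`, `log10_bf`,
#'   `direction` (+1/-1), `infinite` flag (zero posterior density mass at 0).
#' @export
bf_savage_dickey <- function(delta_draws, prior_sd, method = c("normal", "kde")) {
  method <- match.arg(method)
  m <- mean(delta_draws); s <- sd(delta_draws)
  p0_prior <- dnorm(0, 0, prior_sd)
  if (!is.finite(s) || s == 0) {
    return(tibble(delta_mean = m, delta_sd = s, bf = Inf, log10_bf = Inf,
                  direction = sign(m), infinite = TRUE))
  }
  p0_post <- if (method == "normal") dnorm(0, m, s) else {
    d <- stats::density(delta_draws)
    stats::approx(d$x, d$y, xout = 0, yleft = 0, yright = 0)$y
  }
  bf <- p0_prior / p0_post
  tibble(delta_mean = m, delta_sd = s, bf = bf, log10_bf = log10(bf),
         direction = sign(m), infinite = !is.finite(bf))
}

#' Savage-Dickey Bayes factor between two characteristic-expression cells
#'
#' The contrast `delta = beta[cell1] - beta[cell2]` is tested against a point
#' null at zero. By default the condition-level (level-1) draws are
#' contrasted, whose prior is N(0, 2 sigma_l1^2).
#'
#' @param fit A `splotch_fit`.
#' @param group1,mroi1,group2,mroi2 The two cells.
#' @param level `"l1"` or `"l2"`.
#' @param prior_sd Prior sd of the contrast; default
#'   `sqrt(2) * priors$sigma_l1` for level-1 cells.
#' @param method Passed to [bf_savage_dickey()].
#' @return One-row tibble with the contrast label and BF columns.
#' @export
savage_dickey_bf <- function(fit, group1, mroi1, group2, mroi2,
                             level = "l1", prior_sd = NULL,
                             method = "normal") {
  d <- beta_draws(fit, group1, mroi1, level) - beta_draws(fit, group2, mroi2, level)
  if (is.null(prior_sd)) {
    if (level != "l1") stop("supply prior_sd for level-2 contrasts")
    prior_sd <- sqrt(2) * fit$priors$sigma_l1
  }
  res <- bf_savage_dickey(d, prior_sd, method)
  dplyr::bind_cols(tibble(contrast = paste0(group1, ":", mroi1, " - ",
                                            group2, ":", mroi2)), res)
}

#' Call differential expression from Bayes-factor results
#'
#' A contrast is flagged iff its posterior mean is positive (upregulated) and
#' `log10(BF)` strictly exceeds the threshold (default 0.5).
#'
#' @param bf_results Tibble of rows from [savage_dickey_bf()] /
#'   [bf_savage_dickey()].
#' @param threshold log10 Bayes-factor cutoff.
#' @return The input with a logical `de` column.
#' @export
call_de <- function(bf_results, threshold = 0.5) {
  dplyr::mutate(as_tibble(bf_results),
                de = .data$delta_mean > 0 & .data$log10_bf > threshold)
}

#' Region-weighted mean rates from a fit
#'
#' The posterior-mean rate `lambda` averaged over each MROI's spots, weighted
#' by spot total counts (sequencing depth), the weighting used by the
#' detection rule.
#'
#' @param fit A `splotch_fit`.
#' @param weights `"total"` (spot total counts, default) or `"uniform"`.
#' @return Tibble `taxon`, `mroi`, `wmean`.
#' @export
region_weighted_means <- function(fit, weights = c("total", "uniform")) {
  weights <- match.arg(weights)
  sp <- fit$spots
  w <- if (weights == "total") sp$total else rep(1, nrow(sp))
  dplyr::summarise(dplyr::group_by(dplyr::mutate(sp, w = w), .data$mroi),
                   wmean = sum(.data$lambda_mean * .data$w) / sum(.data$w),
                   .groups = "drop") |>
    dplyr::mutate(taxon = fit$taxon, .before = 1)
}

#' Bacteria detection rule
#'
#' A (taxon, MROI) pair is called detected in the colonized (SPF) condition
#' iff its weighted mean count in the region exceeds the maximal weighted
#' mean across all regions of the germ-free (GF) condition for that taxon,
#' and the region holds more than `share_threshold` (default 2%) of the
#' taxon's total count.
#'
#' @param spf_means Tibble `taxon`, `mroi`, `wmean` for the SPF condition.
#' @param gf_means Same for GF; a taxon absent here gets a GF max of 0.
#' @param spf_counts Tibble `taxon`, `mroi`, `count` of raw SPF counts.
#' @param share_threshold Minimum regional share of the taxon's total count.
#' @return Tibble with per-(taxon, mroi) rule terms and a `detected` flag.
#' @export
detect_taxa <- function(spf_means, gf_means, spf_counts, share_threshold = 0.02) {
  gf_means <- as_tibble(gf_means)
  gf_max <- if (!nrow(gf_means)) {
    tibble(taxon = character(), gf_max = double())
  } else {
    dplyr::summarise(dplyr::group_by(gf_means, .data$taxon),
                     gf_max = max(.data$wmean), .groups = "drop")
  }
  shares <- as_tibble(spf_counts) |>
    dplyr::group_by(.data$taxon, .data$mroi) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(share = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  as_tibble(spf_means) |>
    dplyr::left_join(gf_max, by = "taxon") |>
    dplyr::left_join(shares[, c("taxon", "mroi", "share")],
                     by = c("taxon", "mroi")) |>
    dplyr::mutate(
      gf_max = dplyr::coalesce(.data$gf_max, 0),
      share = dplyr::coalesce(.data$share, 0),
      detected = .data$wmean > .data$gf_max & .data$share > share_threshold)
}
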