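## Conditional models for FCS imputation.
##
## Binary:  ridge-penalized logistic regression (K = 2 multinomial case).
## Nominal: ridge-penalized multinomial logistic regression (stands in
##          for the discriminant function some software uses).
## Ordinal: ridge-penalized proportional-odds logistic regression
##          (own Newton solver; MASS::polr serves as an independent
##          oracle in the test suite).
##
## All engines return the penalized MLE and the inverse penalized observed
## information, so imputations can be drawn with parameter perturbation
## from the approximate posterior (proper imputation). The ridge penalty
## is fixed and weakly informative; it also resolves perfect separation
## and empty dummy columns.

RIDGE_LAMBDA <- 1e-4  # penalty is 0.5 * lambda * n * ||coef||^2

# Newton solver for ridge multinomial logistic regression.
# X: n x p design (with intercept column); y: integer in 1..K; K >= 2.
ridge_multinom <- function(X, y, K, w = NULL, lambda = RIDGE_LAMBDA,
                           maxit = 50L, tol = 1e-7, start = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  pen <- lambda * n
  m <- (K - 1L) * p
  theta <- if (!is.null(start) && length(start) == m) start else rep(0, m)
  Y <- matrix(0, n, K - 1L)
  for (k in 2:K) Y[, k - 1L] <- as.numeric(y == k)
  H <- matrix(0, m, m)
  for (it in seq_len(maxit)) {
    B <- matrix(theta, p, K - 1L)
    eta <- X %*% B
    den <- 1 + rowSums(exp(eta))
    P <- exp(eta) / den                       # n x (K-1), probs of levels 2..K
    grad <- as.vector(crossprod(X, w * (Y - P))) - pen * theta
    for (k in seq_len(K - 1L)) {
      for (l in k:(K - 1L)) {
        wkl <- w * (P[, k] * ((k == l) - P[, l]))
        blk <- crossprod(X, X * wkl)
        ridx <- ((k - 1L) * p + 1L):(k * p)
        cidx <- ((l - 1L) * p + 1L):(l * p)
        H[ridx, cidx] <- blk
        if (l > k) H[cidx, ridx] <- t(blk)
      }
    }
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) stopf("multinomial Newton: singular Hessian")
    sn <- sqrt(sum(step^2))
    if (sn > 10) step <- step * (10 / sn)     # dampen early huge steps
    theta <- theta + step
    if (max(abs(grad)) < tol * n) break
  }
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov)) stopf("multinomial Newton: singular information")
  list(theta = theta, cov = cov, p = p, K = K)
}

multinom_probs <- function(fit, Xnew, theta = fit$theta) {
  B <- matrix(theta, fit$p, fit$K - 1L)
  eta <- Xnew %*% B
  den <- 1 + rowSums(exp(eta))
  cbind(1 / den, exp(eta) / den)              # columns = levels 1..K
}

# Newton solver for the ridge-penalized proportional-odds model
#   P(Y <= k | x) = plogis(zeta_k - x'beta),  k = 1..K-1, zeta increasing.
# X must NOT contain an intercept column (the cutpoints play that role).
# Only beta is penalized. Parameters are ordered (beta, zeta); the
# ordering of zeta is preserved by step halving.
ridge_ordinal <- function(X, y, K, w = NULL, lambda = RIDGE_LAMBDA,
                          maxit = 50L, tol = 1e-7, start = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  pen <- lambda * n
  if (!is.null(start) && length(start$beta) == p &&
      length(start$zeta) == K - 1L) {
    beta <- start$beta
    zeta <- start$zeta
  } else {
    cum <- cumsum(tapply(w, factor(y, levels = 1:K), sum,
                         default = 0))[1:(K - 1L)]
    zeta <- stats::qlogis(pmin(pmax(cum / sum(w), 1e-4), 1 - 1e-4))
    zeta <- cummax(zeta + seq_len(K - 1L) * 1e-9)
    beta <- rep(0, p)
  }
  up <- y                                     # index of upper cut (K -> none)
  lo <- y - 1L                                # index of lower cut (0 -> none)
  has_up <- up <= K - 1L
  has_lo <- lo >= 1L
  iup <- which(has_up); ilo <- which(has_lo)
  ia_k <- lapply(1:(K - 1L), function(k) which(y == k))       # rows with up=k
  ib_k <- lapply(1:(K - 1L), function(k) which(y == k + 1L))  # rows with lo=k
  loglik_terms <- function(beta, zeta) {
    eta <- as.vector(X %*% beta)
    ga <- rep(1, n); gb <- rep(0, n)
    ga[iup] <- expit(zeta[up[iup]] - eta[iup])
    gb[ilo] <- expit(zeta[lo[ilo]] - eta[ilo])
    list(eta = eta, ga = ga, gb = gb, pr = pmax(ga - gb, 1e-12))
  }
  m <- p + K - 1L
  H <- matrix(0, m, m)
  lt <- loglik_terms(beta, zeta)
  for (it in seq_len(maxit)) {
    ga <- lt$ga; gb <- lt$gb; pr <- lt$pr
    u <- rep(0, n); v <- rep(0, n)
    u[iup] <- (ga * (1 - ga))[iup]            # d ga / d(cut)
    v[ilo] <- (gb * (1 - gb))[ilo]
    du <- u * (1 - 2 * ga)                    # second derivative terms
    dv <- v * (1 - 2 * gb)
    laa <- du / pr - (u / pr)^2
    lbb <- -dv / pr - (v / pr)^2
    lab <- u * v / pr^2
    la <- u / pr                              # d log p / d a
    lb <- -v / pr
    # gradient
    g_beta <- as.vector(crossprod(X, -w * (la + lb))) - pen * beta
    gz <- vapply(1:(K - 1L), function(k)
      sum(w[ia_k[[k]]] * la[ia_k[[k]]]) + sum(w[ib_k[[k]]] * lb[ib_k[[k]]]),
      numeric(1))
    grad <- c(g_beta, gz)
    # Hessian blocks (a and b both depend on beta through -x)
    sbb <- laa + 2 * lab + lbb
    H[1:p, 1:p] <- crossprod(X, X * (w * sbb))
    Hbz <- matrix(0, p, K - 1L)
    Hzz <- matrix(0, K - 1L, K - 1L)
    for (k in 1:(K - 1L)) {
      ia <- ia_k[[k]]
      ib <- ib_k[[k]]
      ck <- rep(0, n)
      ck[ia] <- ck[ia] + (laa + lab)[ia]
      ck[ib] <- ck[ib] + (lbb + lab)[ib]
      Hbz[, k] <- -as.vector(crossprod(X, w * ck))
      Hzz[k, k] <- sum(w[ia] * laa[ia]) + sum(w[ib] * lbb[ib])
      if (k < K - 1L) {
        # cross term zeta_k, zeta_{k+1}: rows with y = k+1 (up=k+1, lo=k)
        ic <- ib_k[[k]]
        Hzz[k, k + 1L] <- Hzz[k + 1L, k] <- sum(w[ic] * lab[ic])
      }
    }
    H[1:p, p + 1:(K - 1L)] <- Hbz
    H[p + 1:(K - 1L), 1:p] <- t(Hbz)
    H[p + 1:(K - 1L), p + 1:(K - 1L)] <- Hzz
    diag(H)[1:p] <- diag(H)[1:p] + pen
    Hn <- -H                                  # negated: positive definite
    diag(Hn) <- diag(Hn) + 1e-10
    step <- tryCatch(solve(Hn, grad), error = function(e) NULL)
    if (is.null(step)) stopf("ordinal Newton: singular Hessian")
    sn <- sqrt(sum(step^2))
    if (sn > 10) step <- step * (10 / sn)
    ll0 <- sum(w * log(lt$pr)) - 0.5 * pen * sum(beta^2)
    ok <- FALSE
    for (half in 0:20) {
      bn <- beta + step[1:p] ; zn <- zeta + step[p + 1:(K - 1L)]
      if (!is.unsorted(zn)) {
        lt_c <- loglik_terms(bn, zn)
        if (sum(w * log(lt_c$pr)) - 0.5 * pen * sum(bn^2) >= ll0 - 1e-10) {
          ok <- TRUE; break
        }
      }
      step <- step / 2
    }
    if (!ok) break
    beta <- bn; zeta <- zn; lt <- lt_c
    if (max(abs(grad)) < tol * n) break
  }
  cov <- tryCatch(solve(Hn), error = function(e) NULL)
  if (is.null(cov)) stopf("ordinal Newton: singular information")
  list(beta = beta, zeta = zeta, cov = cov, p = p, K = K,
       loglik = sum(w * log(lt$pr)))
}

ordinal_probs <- function(fit, Xnew, beta = fit$beta, zeta = fit$zeta) {
  eta <- as.vector(Xnew %*% beta)
  K <- fit$K
  cum <- vapply(zeta, function(z) stats::plogis(z - eta), numeric(length(eta)))
  cum <- cbind(matrix(cum, ncol = K - 1L), 1)
  probs <- cum - cbind(0, cum[, -K, drop = FALSE])
  pmax(probs, 0)
}

# Draw one category index per row from a probability matrix (rows sum ~1).
draw_categories <- function(probs, K = ncol(probs)) {
  probs <- probs / rowSums(probs)
  U <- upper.tri(matrix(0, K, K), diag = TRUE) * 1
  cp <- probs %*% U                           # row-wise cumulative sums
  idx <- rowSums(cp < stats::runif(nrow(probs))) + 1L
  pmin(idx, K)
}

# Fit a conditional model for one incomplete variable and return a
# closure that draws imputations (with fresh parameter perturbation per
# call). `obs`/`mis` index rows of the shared design matrix `X` (which
# includes an intercept column). Falls back to an observed-marginal draw
# on numerical failure; the engine actually used is recorded in
# attribute "engine".
conditional_sampler <- function(entry, y, X, obs, mis, w = NULL,
                                perturb = TRUE, start = NULL, tol = 1e-5) {
  y_int <- as.integer(droplevels(y[obs]))
  lev_obs <- levels(droplevels(y[obs]))
  Kobs <- length(lev_obs)
  wobs <- if (is.null(w)) NULL else w[obs]
  if (Kobs < 2L)
    return(structure(function() rep(lev_obs[1L], length(mis)),
                     engine = "constant"))
  mode_fallback <- function() {
    p <- as.vector(table(y_int)) / length(y_int)
    structure(function() {
      probs <- matrix(p, length(mis), Kobs, byrow = TRUE)
      lev_obs[draw_categories(probs)]
    }, engine = "marginal_draw")
  }
  if (entry$type == "ordinal" && Kobs >= 3L) {
    fit <- tryCatch(ridge_ordinal(X[obs, -1L, drop = FALSE], y_int, Kobs,
                                  w = wobs, start = start, tol = tol),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      ch <- tryCatch(chol(fit$cov), error = function(e) NULL)
      return(structure(function() {
        beta <- fit$beta; zeta <- fit$zeta
        if (perturb && !is.null(ch)) {
          for (try in 1:10) {
            d <- as.vector(t(ch) %*% stats::rnorm(nrow(ch)))
            zn <- fit$zeta + d[fit$p + seq_len(Kobs - 1L)]
            if (!is.unsorted(zn)) {
              beta <- fit$beta + d[seq_len(fit$p)]; zeta <- zn; break
            }
          }
        }
        probs <- ordinal_probs(fit, X[mis, -1L, drop = FALSE], beta, zeta)
        lev_obs[draw_categories(probs)]
      }, engine = "ridge_ordinal",
         params = list(beta = fit$beta, zeta = fit$zeta)))
    }
  }
  # binary, nominal, and ordinal fallback: ridge multinomial Newton
  fit <- tryCatch(ridge_multinom(X[obs, , drop = FALSE], y_int, Kobs, w = wobs,
                                 start = if (is.numeric(start)) start,
                                 tol = tol),
                  error = function(e) NULL)
  if (is.null(fit)) return(mode_fallback())
  ch <- tryCatch(chol(fit$cov), error = function(e) NULL)
  structure(function() {
    theta <- fit$theta
    if (perturb && !is.null(ch))
      theta <- theta + as.vector(t(ch) %*% stats::rnorm(length(theta)))
    probs <- multinom_probs(fit, X[mis, , drop = FALSE], theta)
    lev_obs[draw_categories(probs)]
  }, engine = if (entry$type == "binary") "ridge_logistic" else "ridge_multinom",
     params = fit$theta)
}
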