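# Independent closed-form oracles, coded from the textbook formulas and kept
# separate from the package's fitting path (normal equations vs lm's QR).

oracle_ols <- function(X, y) {
  Z <- cbind(1, X)
  xtx_inv <- solve(t(Z) %*% Z)
  beta <- xtx_inv %*% t(Z) %*% y
  resid <- y - Z %*% beta
  rss <- sum(resid^2)
  n <- length(y)
  p <- ncol(Z)
  list(
    beta = as.vector(beta),
    rss = rss,
    sigma2 = rss / (n - p),
    df = n - p,
    xtx_inv = xtx_inv,
    loglik = -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  )
}

oracle_bic <- function(loglik, n, d) -2 * loglik + log(n) * d

# one-sided upper prediction bound / two-sided interval at x0 (vector, no
# intercept term)
oracle_pi <- function(or, x0, level = 0.95, side = "upper") {
  z0 <- c(1, x0)
  q <- if (side == "upper") level else (1 + level) / 2
  half <- qt(q, or$df) * sqrt(or$sigma2 * (1 + drop(t(z0) %*% or$xtx_inv %*% z0)))
  point <- drop(t(z0) %*% or$beta)
  c(point = point, lower = point - half, upper = point + half)
}

# exhaustive best-subset oracle over blocks: min-RSS per size, then min BIC
oracle_exhaustive_select <- function(table, blocks, max_size = length(blocks)) {
  nb <- length(blocks)
  blocks <- blocks[order(names(blocks))]
  sizes <- 0:min(max_size, nb)
  best <- lapply(sizes, function(k) list(rss = Inf, set = character(0)))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), nb))
  y <- table$error_abs
  for (i in seq_len(nrow(subsets))) {
    inc <- unlist(subsets[i, ])
    k <- sum(inc)
    if (k > max(sizes)) next
    cols <- unlist(blocks[inc], use.names = FALSE)
    rss <- if (k == 0) {
      sum((y - mean(y))^2)
    } else {
      sum(lm(y ~ ., data = cbind(y = y, table[cols]))$residuals^2)
    }
    if (rss < best[[k + 1]]$rss - 1e-9) {
      best[[k + 1]] <- list(rss = rss, set = sort(names(blocks)[inc]))
    }
  }
  bics <- vapply(seq_along(best), function(i) {
    ddgbounds::bic(fit_ols(table, unlist(blocks[best[[i]]$set], use.names = FALSE)))
  }, numeric(1))
  chosen <- 1L
  for (i in seq_along(bics)) if (bics[i] < bics[chosen] - 1e-9) chosen <- i
  list(chosen = best[[chosen]]$set, best = best, bics = bics)
}

# small random regression fixture with a grouping label
random_fixture <- function(n = 40, p = 3, n_systems = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- rnorm(p)
  y <- 1 + drop(X %*% beta) + rnorm(n, 0, 0.5)
  out <- tibble::as_tibble(as.data.frame(X))
  out$error_abs <- abs(y)
  out$system_id <- rep(sprintf("S%02d", seq_len(n_systems)), length.out = n)
  out
}
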