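# Independent oracles: regression-residual partial correlation and
# exhaustive simple-path enumeration for shortest paths, betweenness and
# local efficiency. These deliberately share no code with the package.

# partial correlation of columns i and j given all the others, via the
# correlation of the residuals of two linear regressions
oracle_partial_residual <- function(x) {
  n <- ncol(x)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      others <- x[, -c(i, j), drop = FALSE]
      ri <- stats::lm.fit(cbind(1, others), x[, i])$residuals
      rj <- stats::lm.fit(cbind(1, others), x[, j])$residuals
      out[i, j] <- out[j, i] <- stats::cor(ri, rj)
    }
  }
  out
}

# exhaustive enumeration of all simple paths between every pair; edge
# lengths are 1/weight. Returns the distance matrix and raw betweenness
# (fractional shortest-path membership summed over unordered pairs).
oracle_paths <- function(w, tol = 1e-9) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  adj <- lapply(seq_len(n), function(i) which(w[i, ] > 0))
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      best <- Inf
      paths <- list()
      rec <- function(v, visited, d) {
        if (d > best + tol) return(invisible())
        if (v == t) {
          if (d < best - tol) {
            best <<- d
            paths <<- list(visited)
          } else {
            paths[[length(paths) + 1L]] <<- visited
          }
          return(invisible())
        }
        for (u in adj[[v]]) {
          if (!(u %in% visited)) rec(u, c(visited, u), d + len[v, u])
        }
      }
      rec(s, s, 0)
      if (is.finite(best)) {
        # drop paths that were recorded before a shorter one was found
        keep <- vapply(paths, function(p) {
          d <- sum(len[cbind(p[-length(p)], p[-1])])
          abs(d - best) <= tol * max(1, best)
        }, logical(1))
        paths <- paths[keep]
        dist[s, t] <- dist[t, s] <- best
        total <- length(paths)
        through <- table(unlist(lapply(paths, function(p) {
          p[-c(1L, length(p))]
        })))
        if (length(through) > 0) {
          idx <- as.integer(names(through))
          bc[idx] <- bc[idx] + as.numeric(through) / total
        }
      }
    }
  }
  list(dist = dist, betweenness = bc)
}

# independent local-efficiency reimplementation on top of oracle_paths
oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(w[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- w[nb, nb, drop = FALSE]
    d <- oracle_paths(sub)$dist
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    out[v] <- sum(inv) / (k * (k - 1))
  }
  out
}

# textbook two-sample t (pooled and Welch)
oracle_t <- function(a, b, pooled = TRUE) {
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs(t), df)
  c(t = t, df = df, p = p)
}

# textbook Pearson r with the t-based p-value
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# balanced 2x2 mixed-design ANOVA by explicit sums of squares
# (subjects crossed with condition, nested in group)
oracle_mixed_anova_balanced <- function(value, subject, group, condition) {
  stopifnot(length(unique(table(group))) == 1)  # balanced groups only
  y <- value
  gm <- mean(y)
  cell <- tapply(y, list(group, condition), mean)
  g_mean <- tapply(y, group, mean)
  c_mean <- tapply(y, condition, mean)
  s_mean <- tapply(y, subject, mean)
  n_per_group <- length(unique(subject)) / 2
  n_cond <- 2
  subj_group <- tapply(as.character(group), subject, function(g) g[1])
  ss_group <- n_per_group * n_cond * sum((g_mean - gm)^2)
  ss_subj_within <- n_cond *
    sum((s_mean - g_mean[subj_group[names(s_mean)]])^2)
  ss_cond <- 2 * n_per_group * sum((c_mean - gm)^2)
  resid_cell <- sweep(sweep(cell, 1, g_mean), 2, c_mean) + gm
  ss_int <- n_per_group * sum(resid_cell^2)
  ss_total <- sum((y - gm)^2)
  ss_err <- ss_total - ss_group - ss_subj_within - ss_cond - ss_int
  df_subj <- 2 * (n_per_group - 1)
  list(F_group = (ss_group / 1) / (ss_subj_within / df_subj),
       F_cond = (ss_cond / 1) / (ss_err / df_subj),
       F_int = (ss_int / 1) / (ss_err / df_subj))
}
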