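# Shared fixtures and independent oracles, all built in code.

small_config <- function(seed = 101, ...) {
  args <- list(
    n_districts = 20, women_per_district = 40, seed = seed,
    geography = utils::modifyList(default_geography(),
                                  list(nx = 5, ny = 5, n_facilities = 3))
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# ten hand-built records: rows 2, 5, 7, 9 are non-users; row 4 is a
# pregnant user -> the filter keeps 5
filter_fixture <- function() {
  data.frame(
    woman_id = sprintf("W%02d", 1:10),
    used_any_method = c("yes", "no", "yes", "yes", "no",
                        "yes", "no", "yes", "no", "yes"),
    pregnant_now = c("no", "no", "no", "yes", "no",
                     "no", "yes", "no", "no", "no"),
    stringsAsFactors = FALSE
  )
}

# six records with a hand-tallied 3x2 cross-tab
crosstab_fixture <- function() {
  data.frame(
    grp = factor(c("a", "a", "b", "b", "b", "c"), levels = c("a", "b", "c")),
    outcome_modern = c(1L, 0L, 1L, 1L, 0L, 0L)
  )
}

# brute-force Pearson chi-square
chisq_oracle <- function(O) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# VIF by explicit normal equations
vif_oracle <- function(X) {
  vapply(seq_len(ncol(X)), function(k) {
    yk <- X[, k]
    Z <- cbind(1, X[, -k, drop = FALSE])
    b <- solve(crossprod(Z), crossprod(Z, yk))
    r2 <- 1 - sum((yk - Z %*% b)^2) / sum((yk - mean(yk))^2)
    1 / (1 - r2)
  }, numeric(1))
}

# marginal log-likelihood for ONE cluster by dense trapezoid integration
# over u in [-10 s, 10 s]
trapezoid_loglik_1cluster <- function(beta, sigma_u, y, X, n_grid = 20001) {
  u <- seq(-10 * sigma_u, 10 * sigma_u, length.out = n_grid)
  eta <- drop(X %*% beta)
  lg <- vapply(u, function(uu) {
    lp <- eta + uu
    sum(y * plogis(lp, log.p = TRUE) + (1 - y) * plogis(-lp, log.p = TRUE))
  }, numeric(1))
  f <- exp(lg) * dnorm(u, 0, sigma_u)
  h <- u[2] - u[1]
  log(h * (sum(f) - (f[1] + f[n_grid]) / 2))
}

# exhaustive shortest path between all node pairs by path enumeration
# (graphs with <= 8 nodes); edges: data.frame(from, to, w), undirected
brute_force_shortest <- function(nodes, edges, sources) {
  adj <- lapply(nodes, function(v) {
    i <- which(edges$from == v | edges$to == v)
    data.frame(to = ifelse(edges$from[i] == v, edges$to[i], edges$from[i]),
               w = edges$w[i], stringsAsFactors = FALSE)
  })
  names(adj) <- nodes
  best <- setNames(rep(Inf, length(nodes)), nodes)
  walk <- function(v, visited, cost) {
    if (cost < best[v]) best[v] <<- cost
    a <- adj[[v]]
    for (i in seq_len(nrow(a))) {
      if (!a$to[i] %in% visited) {
        walk(a$to[i], c(visited, a$to[i]), cost + a$w[i])
      }
    }
  }
  for (s in sources) walk(s, s, 0)
  best
}

# exact Jenks by enumerating every way to cut sorted values into k runs
jenks_brute_ssd <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(x) sum((x - mean(x))^2)
  if (k == 1) return(ssd(v))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- sum(vapply(seq_len(k), function(c)
      ssd(v[(b[c] + 1):b[c + 1]]), numeric(1)))
    if (tot < best) best <- tot
  }
  best
}

# tiny road fixture: 4 segments in a line, known classes/lengths
line_roads <- function(lengths = c(10, 20, 30, 40),
                       classes = c("primary", "secondary", "tertiary", "tracks")) {
  x <- cumsum(c(0, lengths))
  segs <- lapply(seq_along(lengths), function(i)
    rbind(c(x[i], 0), c(x[i + 1], 0)))
  out <- data.frame(segment_id = sprintf("S%02d", seq_along(lengths)),
                    road_class = classes, stringsAsFactors = FALSE)
  out$geometry <- segs
  out
}

# random connected graph with <= n_nodes nodes laid out on a line of
# segments plus random chords, returned as a road data.frame
random_small_roads <- function(n_nodes, n_extra = 2) {
  pts <- cbind(seq_len(n_nodes) * 10, runif(n_nodes, -5, 5))
  segs <- lapply(seq_len(n_nodes - 1), function(i) pts[c(i, i + 1), ])
  pairs <- t(utils::combn(n_nodes, 2))
  pairs <- pairs[pairs[, 2] - pairs[, 1] > 1, , drop = FALSE]
  if (nrow(pairs) > 0 && n_extra > 0) {
    take <- pairs[sample.int(nrow(pairs), min(n_extra, nrow(pairs))), ,
                  drop = FALSE]
    for (i in seq_len(nrow(take))) {
      segs[[length(segs) + 1]] <- pts[take[i, ], ]
    }
  }
  cls <- sample(names(default_speeds()), length(segs), replace = TRUE)
  out <- data.frame(segment_id = sprintf("S%02d", seq_along(segs)),
                    road_class = cls, stringsAsFactors = FALSE)
  out$geometry <- segs
  out
}
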