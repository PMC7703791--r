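# Independent oracles used across the test suite. These deliberately avoid
# the package's own algorithms: the dip oracle solves small linear programs
# over explicit unimodal-CDF candidates, and the drop-search oracle replays
# the published rules step by step.

# Exact dip statistic by brute force: for each candidate mode t (a data
# value), minimise the sup-deviation d over piecewise-linear CDFs that are
# convex left of v_t, may jump at v_t (an atom at the mode) and are concave
# afterwards. One LP per mode via boot::simplex; minimum over modes.
dip_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  v <- unique(x)
  q <- length(v)
  if (q == 1L) return(0)
  u <- vapply(v, function(z) sum(x < z), numeric(1L)) / n
  l <- vapply(v, function(z) sum(x <= z), numeric(1L)) / n
  dx <- diff(v)

  best <- Inf
  nv <- q + 2L                      # g_1..g_q, gpre (left limit at mode), d
  iD <- nv
  iP <- q + 1L
  slope <- function(i) {
    r <- numeric(nv); r[i] <- -1 / dx[i]; r[i + 1] <- 1 / dx[i]; r
  }
  for (t in seq_len(q)) {
    le <- list(); ble <- c(); ge <- list(); bge <- c()
    addle <- function(r, b) { le[[length(le) + 1L]] <<- r; ble <<- c(ble, b) }
    addge <- function(r, b) { ge[[length(ge) + 1L]] <<- r; bge <<- c(bge, b) }
    for (i in seq_len(q)) {
      if (i == t) {
        r <- numeric(nv); r[iP] <- 1; r[iD] <- -1; addle(r, u[t])
        r <- numeric(nv); r[iP] <- 1; r[iD] <- 1;  addge(r, u[t])
        r <- numeric(nv); r[i] <- 1; r[iD] <- -1;  addle(r, l[t])
        r <- numeric(nv); r[i] <- 1; r[iD] <- 1;   addge(r, l[t])
      } else {
        r <- numeric(nv); r[i] <- 1; r[iD] <- -1; addle(r, u[i])
        r <- numeric(nv); r[i] <- 1; r[iD] <- 1;  addge(r, l[i])
      }
    }
    r <- numeric(nv); r[iP] <- 1; r[t] <- -1; addle(r, 0)   # jump upward
    sl_into_pre <- if (t >= 2L) {
      r <- numeric(nv)
      r[t - 1L] <- -1 / dx[t - 1L]; r[iP] <- 1 / dx[t - 1L]
      r
    } else NULL
    if (t >= 3L) {
      for (i in seq_len(t - 3L)) addle(slope(i) - slope(i + 1L), 0)
      addle(slope(t - 2L) - sl_into_pre, 0)
    }
    if (t <= q - 2L) for (i in t:(q - 2L)) addle(slope(i + 1L) - slope(i), 0)
    if (t >= 2L) addge(sl_into_pre, 0) else addge(slope(1L), 0)
    if (t <= q - 1L) addge(slope(q - 1L), 0)
    sol <- try(boot::simplex(a = { a <- numeric(nv); a[iD] <- 1; a },
                             A1 = do.call(rbind, le), b1 = ble,
                             A2 = do.call(rbind, ge), b2 = bge,
                             maxi = FALSE,
                             n.iter = 100 * (length(ble) + length(bge))),
               silent = TRUE)
    if (!inherits(sol, "try-error") && sol$solved == 1 && sol$value < best)
      best <- sol$value
  }
  best
}

# Literal step-by-step replay of the last-substantial-drop search rules:
# skip d1, store d2, scan forward replacing the stored drop whenever a
# candidate is at least f-fold more negative, give up once the scan is more
# than cmax positions past the stored drop.
last_drop_replay <- function(d, cmax = 7, f = 2) {
  stored <- 2L
  j <- 3L
  while (j <= length(d)) {
    if (j - stored > cmax) break
    if (d[stored] * f > d[j]) stored <- j
    j <- j + 1L
  }
  stored
}

# brute-force pairwise Euclidean distances (per-pair sqrt-of-squares loop)
dist_loop <- function(x) {
  n <- ncol(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((x[, i] - x[, j])^2))
  d
}
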