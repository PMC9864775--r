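# Independent brute-force reference implementations used only by the tests.
# Plain scalar loops / graph components, no code shared with the package
# internals; any disagreement with the optimized path fails the suite.

ORACLE_DIRS <- local({
  d <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    v <- c(dx, dy, dz)
    if (all(v == 0)) next
    nz <- v[v != 0]
    if (nz[1] > 0) d[[length(d) + 1]] <- v  # first nonzero positive
  }
  do.call(rbind, d)
})

# squared-distance-free helpers
o_in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

o_glcm_matrix <- function(lv, dist) {
  d <- dim(lv)
  ng <- max(lv)
  out <- array(0L, c(ng, ng, nrow(ORACLE_DIRS)))
  for (k in seq_len(nrow(ORACLE_DIRS))) {
    off <- ORACLE_DIRS[k, ] * dist
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      i <- lv[x, y, z]
      if (i == 0) next
      q <- c(x, y, z) + off
      if (!o_in_bounds(q, d)) next
      j <- lv[q[1], q[2], q[3]]
      if (j == 0) next
      out[i, j, k] <- out[i, j, k] + 1L
      out[j, i, k] <- out[j, i, k] + 1L
    }
  }
  out
}

o_glrlm_matrix <- function(lv) {
  d <- dim(lv)
  ng <- max(lv)
  lmax <- max(d)
  out <- array(0L, c(ng, lmax, nrow(ORACLE_DIRS)))
  for (k in seq_len(nrow(ORACLE_DIRS))) {
    off <- ORACLE_DIRS[k, ]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      i <- lv[x, y, z]
      if (i == 0) next
      prev <- c(x, y, z) - off
      if (o_in_bounds(prev, d) && lv[prev[1], prev[2], prev[3]] == i) next
      len <- 0L
      p <- c(x, y, z)
      while (o_in_bounds(p, d) && lv[p[1], p[2], p[3]] == i) {
        len <- len + 1L
        p <- p + off
      }
      out[i, len, k] <- out[i, len, k] + 1L
    }
  }
  out
}

# zones via igraph connected components over 26-adjacent equal-level voxels
o_glszm_zones <- function(lv) {
  d <- dim(lv)
  idx <- which(lv > 0)
  if (length(idx) == 0) return(data.frame(level = integer(), size = integer()))
  pos <- arrayInd(idx, d)
  key <- function(p) paste(p, collapse = ",")
  id <- stats::setNames(seq_along(idx), apply(pos, 1, key))
  edges <- c()
  for (r in seq_along(idx)) {
    p <- pos[r, ]
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- p + c(dx, dy, dz)
      if (!o_in_bounds(q, d)) next
      if (lv[q[1], q[2], q[3]] != lv[p[1], p[2], p[3]]) next
      r2 <- id[[key(q)]]
      if (!is.null(r2) && r2 > r) edges <- c(edges, r, r2)
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  data.frame(level = lv[idx][match(seq_len(comp$no), comp$membership)],
             size = as.integer(comp$csize))
}

o_ngtdm <- function(lv, dist) {
  d <- dim(lv)
  ng <- max(lv)
  s <- numeric(ng); n <- numeric(ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    i <- lv[x, y, z]
    if (i == 0) next
    nb <- c()
    for (dz in -dist:dist) for (dy in -dist:dist) for (dx in -dist:dist) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!o_in_bounds(q, d)) next
      l2 <- lv[q[1], q[2], q[3]]
      if (l2 > 0) nb <- c(nb, l2)
    }
    if (length(nb) > 0) {
      s[i] <- s[i] + abs(i - mean(nb))
      n[i] <- n[i] + 1
    }
  }
  cbind(s, n)
}

o_gldm_matrix <- function(lv, dist, alpha = 0) {
  d <- dim(lv)
  ng <- max(lv)
  ndmax <- (2 * dist + 1)^3 - 1
  out <- matrix(0L, ng, ndmax + 1)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    i <- lv[x, y, z]
    if (i == 0) next
    dep <- 0L
    for (dz in -dist:dist) for (dy in -dist:dist) for (dx in -dist:dist) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!o_in_bounds(q, d)) next
      l2 <- lv[q[1], q[2], q[3]]
      if (l2 > 0 && abs(l2 - i) <= alpha) dep <- dep + 1L
    }
    out[i, dep + 1L] <- out[i, dep + 1L] + 1L
  }
  out
}

# ---- oracle feature formulas (scalar-loop style) ---------------------------

o_glcm_features_one <- function(C) {
  ng <- nrow(C)
  N <- sum(C)
  if (N == 0) return(NULL)
  P <- C / N
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx2 <- 0; sy2 <- 0
  for (i in 1:ng) { sx2 <- sx2 + (i - mux)^2 * px[i]; sy2 <- sy2 + (i - muy)^2 * py[i] }
  pd <- numeric(ng); ps <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  acc <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0; cor0 <- 0; je <- 0; jent <- 0
  idm <- 0; idmn <- 0; id <- 0; idn <- 0; iv <- 0; ss <- 0
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acc <- acc + p * i * j
    cp <- cp + p * (i + j - mux - muy)^4
    cs <- cs + p * (i + j - mux - muy)^3
    ct <- ct + p * (i + j - mux - muy)^2
    con <- con + p * (i - j)^2
    cor0 <- cor0 + p * i * j
    je <- je + p^2
    if (p > 0) jent <- jent - p * log2(p)
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / ng^2)
    id <- id + p / (1 + abs(i - j))
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) iv <- iv + p / (i - j)^2
    ss <- ss + p * (i - mux)^2
    if (p > 0 && px[i] * py[j] > 0) hxy1 <- hxy1 - p * log2(px[i] * py[j])
    if (px[i] * py[j] > 0) hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
  }
  hx <- 0; hy <- 0
  for (i in 1:ng) {
    if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
    if (py[i] > 0) hy <- hy - py[i] * log2(py[i])
  }
  da <- 0; dent <- 0; dv <- 0
  for (k in 0:(ng - 1)) da <- da + k * pd[k + 1]
  for (k in 0:(ng - 1)) {
    if (pd[k + 1] > 0) dent <- dent - pd[k + 1] * log2(pd[k + 1])
    dv <- dv + (k - da)^2 * pd[k + 1]
  }
  sa <- 0; sent <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * ps[k - 1]
    if (ps[k - 1] > 0) sent <- sent - ps[k - 1] * log2(ps[k - 1])
  }
  occ <- which(px > 0)
  single <- length(occ) < 2
  corr <- if (single || sx2 <= 0 || sy2 <= 0) 1 else (cor0 - mux * muy) / sqrt(sx2 * sy2)
  imc1 <- if (single || max(hx, hy) <= 0) 1 else (jent - hxy1) / max(hx, hy)
  imc2 <- if (single) 1 else sqrt(max(0, 1 - exp(-2 * (hxy2 - jent))))
  mcc <- if (single) 1 else {
    no <- length(occ)
    Q <- matrix(0, no, no)
    for (a in seq_len(no)) for (b in seq_len(no)) {
      for (kk in seq_len(no)) {
        Q[a, b] <- Q[a, b] +
          P[occ[a], occ[kk]] * P[occ[b], occ[kk]] / (px[occ[a]] * py[occ[kk]])
      }
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  c(Autocorrelation = acc, JointAverage = mux, ClusterProminence = cp,
    ClusterShade = cs, ClusterTendency = ct, Contrast = con,
    Correlation = corr, DifferenceAverage = da, DifferenceEntropy = dent,
    DifferenceVariance = dv, JointEnergy = je, JointEntropy = jent,
    Imc1 = imc1, Imc2 = imc2, Idm = idm, Idmn = idmn, Id = id, Idn = idn,
    InverseVariance = iv, MaximumProbability = max(P), SumAverage = sa,
    SumEntropy = sent, SumSquares = ss, MCC = mcc)
}

# 16 size/gray formulas shared by run-length and size-zone matrices
o_size_features <- function(M, np) {
  ns <- sum(M)
  sre <- 0; lre <- 0; lgl <- 0; hgl <- 0
  srl <- 0; srh <- 0; lrl <- 0; lrh <- 0
  glv <- 0; rv <- 0; re <- 0
  mui <- 0; muj <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    p <- M[i, j] / ns
    mui <- mui + p * i
    muj <- muj + p * j
  }
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    mij <- M[i, j]
    p <- mij / ns
    sre <- sre + mij / j^2
    lre <- lre + mij * j^2
    lgl <- lgl + mij / i^2
    hgl <- hgl + mij * i^2
    srl <- srl + mij / (i^2 * j^2)
    srh <- srh + mij * i^2 / j^2
    lrl <- lrl + mij * j^2 / i^2
    lrh <- lrh + mij * i^2 * j^2
    glv <- glv + p * (i - mui)^2
    rv <- rv + p * (j - muj)^2
    if (p > 0) re <- re - p * log2(p)
  }
  gln <- sum(rowSums(M)^2)
  rln <- sum(colSums(M)^2)
  c(sre / ns, lre / ns, gln / ns, gln / ns^2, rln / ns, rln / ns^2, ns / np,
    glv, rv, re, lgl / ns, hgl / ns, srl / ns, srh / ns, lrl / ns, lrh / ns)
}

o_ngtdm_features <- function(sn, ng) {
  s <- sn[, 1]; nv <- sn[, 2]
  Nv <- sum(nv)
  p <- nv / Nv
  occ <- which(p > 0)
  ngp <- length(occ)
  den <- sum(p * s)
  coarse <- if (den > 0) min(1 / den, 1e6) else 1e6
  if (ngp > 1) {
    c1 <- 0; bden <- 0; comp <- 0; str <- 0
    for (i in occ) for (j in occ) {
      c1 <- c1 + p[i] * p[j] * (i - j)^2
      bden <- bden + abs(i * p[i] - j * p[j])
      comp <- comp + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
      str <- str + (p[i] + p[j]) * (i - j)^2
    }
    contrast <- c1 / (ngp * (ngp - 1)) * sum(s) / Nv
    busy <- if (bden > 0) sum(p * s) / bden else 0
    comp <- comp / Nv
    str <- if (sum(s) > 0) str / sum(s) else 0
  } else {
    contrast <- 0; busy <- 0; comp <- 0; str <- 0
  }
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = comp, Strength = str)
}

o_gldm_features <- function(D) {
  nzc <- which(colSums(D) > 0)
  D <- D[, seq_len(max(nzc)), drop = FALSE]
  ns <- sum(D)
  sde <- 0; lde <- 0; lgl <- 0; hgl <- 0
  sdl <- 0; sdh <- 0; ldl <- 0; ldh <- 0
  glv <- 0; dv <- 0; de <- 0
  mui <- 0; muj <- 0
  for (i in seq_len(nrow(D))) for (j in seq_len(ncol(D))) {
    p <- D[i, j] / ns
    mui <- mui + p * i
    muj <- muj + p * j
  }
  for (i in seq_len(nrow(D))) for (j in seq_len(ncol(D))) {
    m <- D[i, j]
    p <- m / ns
    sde <- sde + m / j^2
    lde <- lde + m * j^2
    lgl <- lgl + m / i^2
    hgl <- hgl + m * i^2
    sdl <- sdl + m / (i^2 * j^2)
    sdh <- sdh + m * i^2 / j^2
    ldl <- ldl + m * j^2 / i^2
    ldh <- ldh + m * i^2 * j^2
    glv <- glv + p * (i - mui)^2
    dv <- dv + p * (j - muj)^2
    if (p > 0) de <- de - p * log2(p)
  }
  c(sde / ns, lde / ns, sum(rowSums(D)^2) / ns, sum(colSums(D)^2) / ns,
    sum(colSums(D)^2) / ns^2, glv, dv, de, lgl / ns, hgl / ns, sdl / ns,
    sdh / ns, ldl / ns, ldh / ns)
}

# direction-averaged oracle features per family, on a levels array
o_family_features <- function(lv, family, dist = 1L) {
  np <- sum(lv > 0)
  switch(family,
    glcm = {
      mats <- o_glcm_matrix(lv, dist)
      ng <- max(lv)
      per <- lapply(seq_len(dim(mats)[3]), function(k)
        o_glcm_features_one(matrix(mats[, , k], ng, ng)))
      per <- Filter(Negate(is.null), per)
      if (length(per) == 0) rep(NA_real_, 24) else colMeans(do.call(rbind, per))
    },
    glrlm = {
      mats <- o_glrlm_matrix(lv)
      per <- lapply(seq_len(dim(mats)[3]), function(k) {
        M <- mats[, , k]
        if (sum(M) == 0) return(NULL)
        o_size_features(M, np)
      })
      per <- Filter(Negate(is.null), per)
      colMeans(do.call(rbind, per))
    },
    glszm = {
      z <- o_glszm_zones(lv)
      M <- matrix(0, max(lv), max(z$size))
      for (r in seq_len(nrow(z))) M[z$level[r], z$size[r]] <- M[z$level[r], z$size[r]] + 1
      o_size_features(M, np)
    },
    ngtdm = o_ngtdm_features(o_ngtdm(lv, dist), max(lv)),
    gldm = o_gldm_features(o_gldm_matrix(lv, dist)))
}

# two-way ANOVA by explicit loops + ICC(A,1) formulas, independent of the
# package implementation
o_icc <- function(m, conf = 0.95) {
  n <- nrow(m); k <- ncol(m)
  gm <- 0
  for (i in 1:n) for (j in 1:k) gm <- gm + m[i, j]
  gm <- gm / (n * k)
  rmeans <- numeric(n); cmeans <- numeric(k)
  for (i in 1:n) rmeans[i] <- sum(m[i, ]) / k
  for (j in 1:k) cmeans[j] <- sum(m[, j]) / n
  ssr <- 0; ssc <- 0; sse <- 0
  for (i in 1:n) ssr <- ssr + (rmeans[i] - gm)^2
  ssr <- ssr * k
  for (j in 1:k) ssc <- ssc + (cmeans[j] - gm)^2
  ssc <- ssc * n
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (m[i, j] - rmeans[i] - cmeans[j] + gm)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (mse == 0 && msc == 0) {
    lb <- ub <- 1
  } else {
    alpha <- 1 - conf
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lb <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    ub <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  list(icc = icc, lb = lb, ub = ub, msr = msr, msc = msc, mse = mse)
}

# random discretized-region fixture (<= 6x6x6), possibly with out-of-region
# holes; returns an object the texture functions accept
rand_disc <- function(seed, ng = 4L, p_hole = 0.2) {
  set.seed(seed)
  d <- sample(2:6, 3, replace = TRUE)
  lv <- array(sample.int(ng, prod(d), replace = TRUE), dim = d)
  lv[stats::runif(prod(d)) < p_hole] <- 0L
  if (sum(lv > 0) < 2) lv[c(1, 2)] <- c(1L, ng)
  structure(list(levels = lv, ng = max(lv), bin_width = 1,
                 n_voxels = sum(lv > 0)),
            class = "rr_discretized")
}
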