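# Independent brute-force oracles for the texture features: pair/run
# enumeration by explicit walking, and feature statistics re-derived with
# plain loops. Deliberately written without reuse of the package internals.

oracle_quantize <- function(v, bin_size) pmax(1L, as.integer(floor(v / bin_size)) + 1L)

oracle_directions <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(-1, 1, 0),
        c(1, 0, 1), c(1, 1, 1), c(1, -1, 1), c(0, 0, 1),
        c(0, 1, 1), c(0, -1, 1), c(-1, 0, 1), c(-1, 1, 1),
        c(-1, -1, 1))
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# explicit pair enumeration GLCM for one direction (symmetric, normalized)
oracle_glcm_matrix <- function(lev, mask, v) {
  d <- dim(mask)
  ng <- max(lev[mask])
  M <- matrix(0, ng, ng)
  for (idx in which(mask)) {
    p <- arrayInd(idx, d)[1, ]
    q <- p + v
    if (in_grid(q, d) && mask[q[1], q[2], q[3]]) {
      g1 <- lev[p[1], p[2], p[3]]; g2 <- lev[q[1], q[2], q[3]]
      M[g1, g2] <- M[g1, g2] + 1
      M[g2, g1] <- M[g2, g1] + 1
    }
  }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

# feature statistics by plain double loops
oracle_glcm_stats <- function(P) {
  ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:ng) for (j in 1:ng) { mux <- mux + i * P[i, j]
                                    muy <- muy + j * P[i, j] }
  sdx <- 0; sdy <- 0
  for (i in 1:ng) for (j in 1:ng) { sdx <- sdx + (i - mux)^2 * P[i, j]
                                    sdy <- sdy + (j - muy)^2 * P[i, j] }
  sdx <- sqrt(sdx); sdy <- sqrt(sdy)
  psum <- rep(0, 2 * ng); pdiff <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  lg2 <- function(p) ifelse(p > 0, log2(p), 0)
  f <- numeric(0)
  acc <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0; cor_num <- 0; dis <- 0
  ene <- 0; ent <- 0; h1 <- 0; h2 <- 0; idmn <- 0; idn <- 0; iv <- 0
  vr <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acc <- acc + i * j * p
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    ct <- ct + (i + j - mux - muy)^2 * p
    con <- con + (i - j)^2 * p
    cor_num <- cor_num + i * j * p
    dis <- dis + abs(i - j) * p
    ene <- ene + p^2
    ent <- ent - p * lg2(p)
    h1 <- h1 + p / (1 + abs(i - j))
    h2 <- h2 + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / ng^2)
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) iv <- iv + p / (i - j)^2
    vr <- vr + (i - mux)^2 * p
    hxy1 <- hxy1 - p * lg2(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg2(px[i] * py[j])
  }
  hx <- -sum(px * lg2(px)); hy <- -sum(py * lg2(py))
  sa <- sum((2:(2 * ng)) * psum[2:(2 * ng)])
  se <- -sum(psum * lg2(psum))
  sv <- sum(((2:(2 * ng)) - sa)^2 * psum[2:(2 * ng)])
  de <- -sum(pdiff * lg2(pdiff))
  corr <- if (sdx > 0 && sdy > 0) (cor_num - mux * muy) / (sdx * sdy) else 0
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(autocorrelation = acc, cluster_prominence = cp, cluster_shade = cs,
    cluster_tendency = ct, contrast = con, correlation = corr,
    difference_entropy = de, dissimilarity = dis, energy = ene,
    entropy = ent, homogeneity1 = h1, homogeneity2 = h2, imc1 = imc1,
    imc2 = imc2, idmn = idmn, idn = idn, inverse_variance = iv,
    max_probability = max(P), sum_average = sa, sum_entropy = se,
    sum_variance = sv, variance = vr)
}

oracle_glcm_features <- function(vol, mask, bin_size = 100) {
  lev <- array(oracle_quantize(vol$data, bin_size), dim(vol$data))
  dirs <- oracle_directions()
  acc <- NULL; used <- 0
  for (r in seq_len(nrow(dirs))) {
    P <- oracle_glcm_matrix(lev, mask, dirs[r, ])
    if (is.null(P)) next
    s <- oracle_glcm_stats(P)
    acc <- if (is.null(acc)) s else acc + s
    used <- used + 1
  }
  acc / used
}

# run enumeration by explicit chain walking at stride dist * v
oracle_glrlm_runs <- function(lev, mask, v, dist) {
  d <- dim(mask)
  step <- v * dist
  runs <- list()
  for (idx in which(mask)) {
    p <- arrayInd(idx, d)[1, ]
    prev <- p - step
    g <- lev[p[1], p[2], p[3]]
    # run start: predecessor outside grid, outside mask, or different gray
    starts <- !in_grid(prev, d) || !mask[prev[1], prev[2], prev[3]] ||
      lev[prev[1], prev[2], prev[3]] != g
    if (!starts) next
    len <- 1
    q <- p + step
    while (in_grid(q, d) && mask[q[1], q[2], q[3]] &&
           lev[q[1], q[2], q[3]] == g) {
      len <- len + 1
      q <- q + step
    }
    runs[[length(runs) + 1]] <- c(gray = g, len = len)
  }
  do.call(rbind, runs)
}

oracle_glrlm_stats <- function(runs, n_voxels) {
  nr <- nrow(runs)
  g <- runs[, "gray"]; l <- runs[, "len"]
  c(sre = mean(1 / l^2), lre = mean(l^2),
    gln = sum(table(g)^2) / nr, rln = sum(table(l)^2) / nr,
    rp = nr / n_voxels,
    lglre = mean(1 / g^2), hglre = mean(g^2),
    srlgle = mean(1 / (g^2 * l^2)), srhgle = mean(g^2 / l^2),
    lrlgle = mean(l^2 / g^2), lrhgle = mean(g^2 * l^2))
}

oracle_glrlm_features <- function(vol, mask, distances = 2:5,
                                  bin_size = 100) {
  lev <- array(oracle_quantize(vol$data, bin_size), dim(vol$data))
  dirs <- oracle_directions()
  acc <- NULL; used <- 0
  for (dist in distances) {
    for (r in seq_len(nrow(dirs))) {
      runs <- oracle_glrlm_runs(lev, mask, dirs[r, ], dist)
      s <- oracle_glrlm_stats(runs, sum(mask))
      acc <- if (is.null(acc)) s else acc + s
      used <- used + 1
    }
  }
  acc / used
}
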