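## Independent brute-force oracles for the radiomic features: plain-R
## loop implementations computed directly from the definitions, used to
## cross-check the package's vectorised/compiled path.

oracleFirstOrder <- function(v, binWidth = 25, pixelArea = 1) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  qs <- stats::quantile(v, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
  mid <- v[v >= qs[1] & v <= qs[4]]
  lev <- floor((v - min(v)) / binWidth)
  p <- as.numeric(table(lev)) / n
  c(energy = sum(v^2),
    total_energy = pixelArea * sum(v^2),
    entropy = -sum(p * log2(p)),
    minimum = min(v), p10 = qs[1], p90 = qs[4], maximum = max(v),
    mean = mu, median = stats::median(v), iqr = qs[3] - qs[2],
    range = max(v) - min(v),
    mad = sum(abs(v - mu)) / n,
    rmad = sum(abs(mid - mean(mid))) / length(mid),
    rms = sqrt(sum(v^2) / n),
    sd = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2))
}

## pair enumeration for one offset; returns symmetric counts
oracleGlcmMatrix <- function(lv, ng, dx, dy) {
  P <- matrix(0, ng, ng)
  for (r in seq_len(nrow(lv))) for (c in seq_len(ncol(lv))) {
    a <- lv[r, c]
    if (is.na(a)) next
    r2 <- r + dy; c2 <- c + dx
    if (r2 < 1 || r2 > nrow(lv) || c2 < 1 || c2 > ncol(lv)) next
    b <- lv[r2, c2]
    if (is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

oracleGlcmFeatures <- function(P, ng) {
  p <- P / sum(P)
  px <- rowSums(p)
  mu <- 0; for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  sig2 <- 0; for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (i - mu)^2 * p[i, j]
  pd <- rep(0, ng); ps <- rep(0, 2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + p[i, j]
  }
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  da <- sum((0:(ng - 1)) * pd)
  out <- c(autocorrelation = 0, joint_average = mu, cluster_prominence = 0,
           cluster_shade = 0, cluster_tendency = 0, contrast = 0,
           correlation = 0, difference_average = da,
           difference_entropy = H(pd), difference_variance = 0,
           joint_energy = 0, joint_entropy = H(p), imc1 = 0, imc2 = 0,
           idm = 0, idmn = 0, id = 0, idn = 0, inverse_variance = 0,
           maximum_probability = max(p),
           sum_average = sum((2:(2 * ng)) * ps), sum_entropy = H(ps),
           sum_squares = sig2, mcc = 0)
  for (i in 1:ng) for (j in 1:ng) {
    q <- p[i, j]
    out["autocorrelation"] <- out["autocorrelation"] + i * j * q
    out["cluster_prominence"] <- out["cluster_prominence"] + (i + j - 2 * mu)^4 * q
    out["cluster_shade"] <- out["cluster_shade"] + (i + j - 2 * mu)^3 * q
    out["cluster_tendency"] <- out["cluster_tendency"] + (i + j - 2 * mu)^2 * q
    out["contrast"] <- out["contrast"] + (i - j)^2 * q
    out["joint_energy"] <- out["joint_energy"] + q^2
    out["idm"] <- out["idm"] + q / (1 + (i - j)^2)
    out["idmn"] <- out["idmn"] + q / (1 + ((i - j) / ng)^2)
    out["id"] <- out["id"] + q / (1 + abs(i - j))
    out["idn"] <- out["idn"] + q / (1 + abs(i - j) / ng)
    if (i != j) out["inverse_variance"] <- out["inverse_variance"] + q / (i - j)^2
  }
  for (k in 0:(ng - 1))
    out["difference_variance"] <- out["difference_variance"] + (k - da)^2 * pd[k + 1]
  out["correlation"] <- if (sig2 > 0)
    (out[["autocorrelation"]] - mu^2) / sig2 else 1
  hx <- H(px); hxy <- H(p)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q2 <- px[i] * px[j]
    if (q2 > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(q2)
      hxy2 <- hxy2 - q2 * log2(q2)
    }
  }
  out["imc1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  v2 <- 1 - exp(-2 * (hxy2 - hxy))
  out["imc2"] <- if (v2 > 0) sqrt(v2) else 0
  if (ng > 1 && all(px > 0)) {
    Q <- matrix(0, ng, ng)
    for (i in 1:ng) for (j in 1:ng)
      for (k in 1:ng) Q[i, j] <- Q[i, j] + p[i, k] * p[j, k] / (px[i] * px[k])
    lam <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    out["mcc"] <- sqrt(max(0, lam[2]))
  } else out["mcc"] <- 1
  out
}

oracleGlcm <- function(lv, ng) {
  dirs <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  per <- lapply(dirs, function(d) {
    P <- oracleGlcmMatrix(lv, ng, d[1], d[2])
    if (sum(P) == 0) return(NULL)
    oracleGlcmFeatures(P, ng)
  })
  per <- per[!vapply(per, is.null, TRUE)]
  colMeans(do.call(rbind, per))
}

## explicit run enumeration for one direction
oracleGlrlmMatrix <- function(lv, ng, dx, dy) {
  nr <- nrow(lv); nc <- ncol(lv)
  R <- matrix(0, ng, max(nr, nc))
  for (r0 in 1:nr) for (c0 in 1:nc) {
    rp <- r0 - dy; cp <- c0 - dx
    if (rp >= 1 && rp <= nr && cp >= 1 && cp <= nc) next  # not a line start
    r <- r0; c <- c0; cur <- NA; len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- lv[r, c]
      if (is.na(v)) {
        if (len > 0) R[cur, len] <- R[cur, len] + 1
        cur <- NA; len <- 0
      } else if (!is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (len > 0) R[cur, len] <- R[cur, len] + 1
        cur <- v; len <- 1
      }
      r <- r + dy; c <- c + dx
    }
    if (len > 0) R[cur, len] <- R[cur, len] + 1
  }
  R
}

oracleRunFeatures <- function(R, np) {
  nr <- sum(R)
  ng <- nrow(R); nl <- ncol(R)
  out <- c(sre = 0, lre = 0, gln = 0, glnn = 0, rln = 0, rlnn = 0,
           rp = nr / np, glv = 0, rv = 0, re = 0, lglre = 0, hglre = 0,
           srlgle = 0, srhgle = 0, lrlgle = 0, lrhgle = 0)
  gl <- 0; rl <- 0
  for (i in 1:ng) for (j in 1:nl) {
    q <- R[i, j] / nr
    gl <- gl + i * q; rl <- rl + j * q
    out["sre"] <- out["sre"] + q / j^2
    out["lre"] <- out["lre"] + q * j^2
    out["lglre"] <- out["lglre"] + q / i^2
    out["hglre"] <- out["hglre"] + q * i^2
    out["srlgle"] <- out["srlgle"] + q / (i^2 * j^2)
    out["srhgle"] <- out["srhgle"] + q * i^2 / j^2
    out["lrlgle"] <- out["lrlgle"] + q * j^2 / i^2
    out["lrhgle"] <- out["lrhgle"] + q * i^2 * j^2
    if (q > 0) out["re"] <- out["re"] - q * log2(q)
  }
  for (i in 1:ng) out["gln"] <- out["gln"] + sum(R[i, ])^2
  for (j in 1:nl) out["rln"] <- out["rln"] + sum(R[, j])^2
  out["glnn"] <- out["gln"] / nr^2; out["gln"] <- out["gln"] / nr
  out["rlnn"] <- out["rln"] / nr^2; out["rln"] <- out["rln"] / nr
  for (i in 1:ng) for (j in 1:nl) {
    q <- R[i, j] / nr
    out["glv"] <- out["glv"] + (i - gl)^2 * q
    out["rv"] <- out["rv"] + (j - rl)^2 * q
  }
  out
}

oracleGlrlm <- function(lv, ng) {
  np <- sum(!is.na(lv))
  dirs <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  per <- lapply(dirs, function(d)
    oracleRunFeatures(oracleGlrlmMatrix(lv, ng, d[1], d[2]), np))
  colMeans(do.call(rbind, per))
}

## zones via repeated flood fill (8-connectivity)
oracleZones <- function(lv) {
  nr <- nrow(lv); nc <- ncol(lv)
  seen <- matrix(FALSE, nr, nc)
  zl <- integer(); zs <- integer()
  for (r0 in 1:nr) for (c0 in 1:nc) {
    if (seen[r0, c0] || is.na(lv[r0, c0])) next
    v <- lv[r0, c0]
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(stack)) {
      pt <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        r <- pt[1] + dr; c <- pt[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (seen[r, c] || is.na(lv[r, c]) || lv[r, c] != v) next
        seen[r, c] <- TRUE; stack[[length(stack) + 1]] <- c(r, c)
      }
    }
    zl <- c(zl, v); zs <- c(zs, size)
  }
  cbind(zl, zs)
}

oracleGlszm <- function(lv, ng) {
  np <- sum(!is.na(lv))
  z <- oracleZones(lv)
  nz <- nrow(z)
  maxs <- max(z[, 2])
  Z <- matrix(0, ng, maxs)
  for (k in 1:nz) Z[z[k, 1], z[k, 2]] <- Z[z[k, 1], z[k, 2]] + 1
  f <- oracleRunFeatures(Z, np)   # identical functional form, j = zone size
  names(f) <- c("sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv",
                "zv", "ze", "lglze", "hglze", "salgle", "sahgle",
                "lalgle", "lahgle")
  f
}

oracleNgtdm <- function(lv, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  ni <- rep(0, ng); si <- rep(0, ng)
  for (r in 1:nr) for (c in 1:nc) {
    v <- lv[r, c]
    if (is.na(v)) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.na(lv[r2, c2])) nb <- c(nb, lv[r2, c2])
    }
    if (!length(nb)) next
    ni[v] <- ni[v] + 1
    si[v] <- si[v] + abs(v - mean(nb))
  }
  N <- sum(ni); p <- ni / N
  act <- which(p > 0); ngp <- length(act)
  sps <- sum(p * si)
  coarse <- if (sps > 0) 1 / sps else 1e6
  contrast <- 0; den <- 0; complexity <- 0; strength <- 0
  if (ngp > 1) {
    for (i in act) for (j in act) {
      contrast <- contrast + p[i] * p[j] * (i - j)^2
      den <- den + abs(i * p[i] - j * p[j])
      complexity <- complexity +
        abs(i - j) * (p[i] * si[i] + p[j] * si[j]) / (p[i] + p[j])
      strength <- strength + (p[i] + p[j]) * (i - j)^2
    }
    contrast <- contrast / (ngp * (ngp - 1)) * sum(si) / N
    complexity <- complexity / N
    strength <- if (sum(si) > 0) strength / sum(si) else 0
  }
  busy <- if (ngp > 1 && den > 0) sps / den else 0
  c(coarseness = coarse, contrast = contrast, busyness = busy,
    complexity = complexity, strength = strength)
}

oracleGldm <- function(lv, ng, alpha = 0) {
  nr <- nrow(lv); nc <- ncol(lv)
  np <- sum(!is.na(lv))
  P <- matrix(0, ng, 9)
  for (r in 1:nr) for (c in 1:nc) {
    v <- lv[r, c]
    if (is.na(v)) next
    k <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.na(lv[r2, c2]) && abs(lv[r2, c2] - v) <= alpha) k <- k + 1
    }
    P[v, k + 1] <- P[v, k + 1] + 1   # dependence j = k + 1 (centre counted)
  }
  f <- oracleRunFeatures(P, np)
  out <- c(f[c("sre", "lre", "gln")], dn = unname(f["rln"]),
           dnn = unname(f["rlnn"]), f[c("glv")], dv = unname(f["rv"]),
           de = unname(f["re"]), lgle = unname(f["lglre"]),
           hgle = unname(f["hglre"]), sdlgle = unname(f["srlgle"]),
           sdhgle = unname(f["srhgle"]), ldlgle = unname(f["lrlgle"]),
           ldhgle = unname(f["lrhgle"]))
  names(out)[1:3] <- c("sde", "lde", "gln")
  out
}

## random masked level image for oracle-equivalence checks
randomLevelImage <- function(nr = 8, nc = 8, nLevels = 4, pMask = 0.8) {
  lv <- matrix(sample.int(nLevels, nr * nc, replace = TRUE), nr, nc)
  keep <- matrix(stats::runif(nr * nc) < pMask, nr, nc)
  ## guarantee at least a few pixels
  if (sum(keep) < 4) keep[sample.int(nr * nc, 4)] <- TRUE
  lv[!keep] <- NA_integer_
  lv
}
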