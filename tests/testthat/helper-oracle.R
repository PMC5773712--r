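# Independent brute-force oracle for the feature encoder. Expands the
# component definition literally, term by term, with plain loops and no
# shared code path with the package implementation (only the raw property
# table and the alphabet constant are reused as inputs).

oracle_normalize <- function(raw, R = 1) {
  out <- numeric(20)
  names(out) <- sigscan::AA_ALPHABET
  dmax <- max(raw); dmin <- min(raw)
  for (a in sigscan::AA_ALPHABET) {
    out[a] <- (2 * R / (dmax - dmin)) * (raw[a] - dmax) + R
  }
  out
}

oracle_tables <- function(R = 1) {
  p <- sigscan::aa_properties()
  list(
    oracle_normalize(stats::setNames(p$hydrophobicity, p$residue), R),
    oracle_normalize(stats::setNames(p$hydrophilicity, p$residue), R),
    oracle_normalize(stats::setNames(p$side_chain_mass, p$residue), R)
  )
}

# theta per the three pair functions: contrast on property s = scheme id,
# cross-correlation on (1,2), (1,3), (2,3).
oracle_theta <- function(l, m, scheme_id, tabs) {
  s <- tabs[[scheme_id]]
  ab <- switch(scheme_id, c(1, 2), c(1, 3), c(2, 3))
  a <- tabs[[ab[1]]]; b <- tabs[[ab[2]]]
  first <- sqrt(s[l]^2 * abs(s[l] - s[m])^2)
  abar <- mean(a); bbar <- mean(b)
  ssa <- 0; ssb <- 0
  for (x in sigscan::AA_ALPHABET) {
    ssa <- ssa + (a[x] - abar)^2
    ssb <- ssb + (b[x] - bbar)^2
  }
  cross <- abs((a[l] - abar) * (b[m] - bbar)) / sqrt(ssa * ssb)
  unname(first + cross)
}

# all pairwise theta values for one scheme, evaluated once (pure cache of
# oracle_theta, which stays the literal formula)
oracle_theta_table <- function(scheme_id, tabs) {
  tt <- matrix(0, 20, 20,
               dimnames = list(sigscan::AA_ALPHABET, sigscan::AA_ALPHABET))
  for (l in sigscan::AA_ALPHABET) {
    for (m in sigscan::AA_ALPHABET) {
      tt[l, m] <- oracle_theta(l, m, scheme_id, tabs)
    }
  }
  tt
}

# directed adjacency count of (l, m) by naive double scan
oracle_pair_count <- function(chars, l, m) {
  n <- length(chars)
  total <- 0
  if (n >= 2) {
    for (t in 1:(n - 1)) {
      if (chars[t] == l && chars[t + 1] == m) total <- total + 1
    }
  }
  total
}

oracle_xy <- function(chars, ahat, tt) {
  acc <- 0
  for (k in sigscan::AA_ALPHABET) {
    if (k == ahat) next
    acc <- acc + oracle_pair_count(chars, k, ahat) * tt[k, ahat]
    acc <- acc + oracle_pair_count(chars, ahat, k) * tt[ahat, k]
  }
  acc / 38
}

# the three additive parts of one feature component:
# core = count + (count-1)! * theta(a,a) + sum(internal gaps) * XY
# lead = leading gap * XY ; trail = trailing gap * XY
oracle_component_parts <- function(chars, ahat, tt) {
  pos <- which(chars == ahat)
  lam <- length(pos)
  if (lam == 0) return(c(core = 0, lead = 0, trail = 0))
  n <- length(chars)
  xy <- oracle_xy(chars, ahat, tt)
  internal <- 0
  if (lam >= 2) {
    for (t in 1:(lam - 1)) internal <- internal + (pos[t + 1] - pos[t])
  }
  core <- lam + factorial(lam - 1) * tt[ahat, ahat] + internal * xy
  lead <- if (pos[1] > 1) pos[1] * xy else 0
  trail <- if (pos[lam] < n) (n - pos[lam]) * xy else 0
  c(core = core, lead = lead, trail = trail)
}

oracle_encode <- function(residues, R = 1, theta_tables = NULL) {
  chars <- strsplit(residues, "")[[1]]
  if (is.null(theta_tables)) {
    tabs <- oracle_tables(R)
    theta_tables <- lapply(1:3, oracle_theta_table, tabs = tabs)
  }
  n <- length(chars)
  out <- numeric(0)
  for (scheme_id in 1:3) {
    parts <- sapply(sigscan::AA_ALPHABET, function(a) {
      oracle_component_parts(chars, a, theta_tables[[scheme_id]])
    })
    out <- c(out, parts["core", ], parts["lead", ], parts["trail", ])
  }
  comp <- sapply(sigscan::AA_ALPHABET, function(a) sum(chars == a) / n)
  posm <- sapply(sigscan::AA_ALPHABET, function(a) {
    p <- which(chars == a)
    if (length(p)) mean(p) / n else 0
  })
  unname(c(out, comp, posm))
}

# pairwise-ranking AUC oracle: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == "secretory"]
  sn <- scores[labels == "non_secretory"]
  total <- 0
  for (a in sp) for (b in sn) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(sp) * length(sn))
}

random_sequence <- function(n) {
  paste(sample(sigscan::AA_ALPHABET, n, replace = TRUE), collapse = "")
}
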