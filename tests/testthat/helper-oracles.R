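# Independent brute-force oracles, deliberately written as naive
# peptide-by-peptide / pair-by-pair loops so they share no code with the
# implementations they check.

oracle_distribute <- function(peptides, proteins) {
  cols <- setdiff(names(peptides), c("peptide_id", "protein_ids"))
  ids <- proteins$protein_id
  plist <- strsplit(as.character(peptides$protein_ids), ";")
  out <- matrix(0, length(ids), length(cols), dimnames = list(ids, cols))
  for (r in cols) {
    u <- stats::setNames(numeric(length(ids)), ids)
    for (i in seq_len(nrow(peptides)))
      if (length(plist[[i]]) == 1)
        u[plist[[i]]] <- u[plist[[i]]] + peptides[[r]][i]
    d <- u
    for (i in seq_len(nrow(peptides)))
      if (length(plist[[i]]) > 1) {
        ps <- plist[[i]]
        w <- u[ps]
        w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(ps), length(ps))
        d[ps] <- d[ps] + peptides[[r]][i] * w
      }
    out[, r] <- d
  }
  out
}

# exhaustive three-clause evaluation of the hit filter on one row
oracle_hit <- function(fold, p, present, ctrl_absent,
                       fold_thr = 3, p_thr = 0.05, min_present = 3) {
  clause1 <- (fold >= fold_thr) || ctrl_absent
  clause2 <- p < p_thr
  clause3 <- present >= min_present
  clause1 && clause2 && clause3
}

# event taxonomy by pairwise enumeration of every excursion
oracle_classify <- function(pos, thr = 0.6) {
  n <- length(pos)
  fwd <- bwd <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      fwd <- max(fwd, pos[j] - pos[i])
      bwd <- max(bwd, pos[i] - pos[j])
    }
  if (fwd > thr && bwd > thr) return("diffusive")
  if (abs(pos[n] - pos[1]) >= thr) return("processive")
  "static"
}

oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, p = 2 * stats::pt(-abs(t), df))
}

oracle_student <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(t), n1 + n2 - 2)
}

# Mann-Whitney, normal approximation with tie correction and continuity
oracle_mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  sigma <- sqrt(n1 * n2 / 12 *
                  ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  z <- U - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sigma
  list(statistic = U, p = min(1, 2 * stats::pnorm(-abs(z))))
}

# Dunn's pairwise z tests written out longhand over one pair at a time
oracle_dunn <- function(values, groups, pair) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  t_tab <- table(values)
  corr <- sum(t_tab^3 - t_tab) / (12 * (N - 1))
  m1 <- mean(r[groups == pair[1]])
  m2 <- mean(r[groups == pair[2]])
  n1 <- sum(groups == pair[1]); n2 <- sum(groups == pair[2])
  z <- (m1 - m2) / sqrt((N * (N + 1) / 12 - corr) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# random peptide evidence for small property-test instances
random_peptide_instance <- function(seed, max_proteins = 6,
                                    max_peptides = 10, n_rep = 3) {
  set.seed(seed)
  n_prot <- sample(2:max_proteins, 1)
  n_pep <- sample(2:max_peptides, 1)
  ids <- LETTERS[seq_len(n_prot)]
  plist <- lapply(seq_len(n_pep), function(i) {
    k <- sample(c(1, 1, 1, 2, 3), 1)
    sample(ids, min(k, n_prot))
  })
  peps <- data.frame(peptide_id = sprintf("p%02d", seq_len(n_pep)),
                     protein_ids = vapply(plist, paste, "",
                                          collapse = ";"))
  for (r in seq_len(n_rep))
    peps[[sprintf("bait_%d", r)]] <- stats::rpois(n_pep, 3)
  list(peptides = peps,
       proteins = data.frame(protein_id = ids,
                             length_aa = sample(100:900, n_prot)))
}

# a bare trace data.frame from a position vector
make_trace <- function(pos, frame0 = 0, ch2 = FALSE) {
  data.frame(event_id = "e1",
             frame = frame0 + seq_along(pos) - 1,
             time_s = (frame0 + seq_along(pos) - 1) * 0.4,
             position_um = pos,
             channel2_present = ch2)
}
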