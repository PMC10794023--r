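# Independent oracles for the dual-route checks. These deliberately use
# naive algorithms (string scans, exhaustive enumeration, literal segment
# concatenation) and share no code with the implementation paths they check.

# --- naive two-strand motif scan -------------------------------------------
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

revcomp_chars <- function(ch) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  rev(unname(comp[ch]))
}

scan_one_strand <- function(chars, motif_chars) {
  L <- length(chars); k <- length(motif_chars)
  if (L < k) return(integer())
  ok <- rep(TRUE, L - k + 1L)
  for (j in seq_len(k)) {
    set <- IUPAC_SETS[[motif_chars[j]]]
    win <- chars[j:(L - k + j)]
    ok <- ok & if (length(set) == 1L) win == set else win %in% set
  }
  which(ok)
}

oracle_digest_positions <- function(seq_string, motif, offset) {
  chars <- strsplit(seq_string, "")[[1L]]
  mc <- strsplit(motif, "")[[1L]]
  fwd <- scan_one_strand(chars, mc)             # 1-based starts
  rev_starts <- scan_one_strand(chars, revcomp_chars(mc))
  p <- c(fwd + offset + 1, (rev_starts + length(mc) - 1) - offset - 1)
  p <- p[p > 0 & p <= length(chars)]
  sort(p)
}

# --- exhaustive monotone-matching alignment score --------------------------
oracle_fit_score <- function(q, r, params) {
  n <- length(r); m <- length(q)
  best <- -Inf
  score_of <- function(pairs) {
    s <- nrow(pairs) * params$match_reward
    for (t in seq_len(nrow(pairs) - 1L)) {
      i1 <- pairs[t, 1L]; j1 <- pairs[t, 2L]
      i2 <- pairs[t + 1L, 1L]; j2 <- pairs[t + 1L, 2L]
      expd <- r[i2] - r[i1]; obsd <- q[j2] - q[j1]
      s <- s - params$sizing_error_scale * (obsd - expd)^2 / (expd * 1000) -
        (i2 - i1 - 1L) * params$missed_ref_label_penalty -
        (j2 - j1 - 1L) * params$false_molecule_label_penalty
    }
    s
  }
  extend <- function(pairs) {
    if (nrow(pairs) >= 2L) best <<- max(best, score_of(pairs))
    li <- pairs[nrow(pairs), 1L]; lj <- pairs[nrow(pairs), 2L]
    for (i in seq_len(n)) {
      if (i <= li || i - li - 1L > params$band_max_skips) next
      for (j in seq_len(m)) {
        if (j <= lj || j - lj - 1L > params$band_max_skips) next
        extend(rbind(pairs, c(i, j)))
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    extend(matrix(c(i, j), 1L, 2L))
  }
  best
}

# --- exhaustive penalized-likelihood split search --------------------------
oracle_cluster <- function(x, cfg) {
  xs <- sort(x); n <- length(xs)
  blk <- function(v) {
    mu <- mean(v)
    sd <- max(sqrt(mean((v - mu)^2)), cfg$sigma_floor_bp)
    list(mu = mu, ll = -length(v) / 2 * (log(2 * pi * sd^2) + 1))
  }
  feasible <- function(parts) {
    if (length(parts) > 1L) {
      if (any(lengths(parts) < cfg$min_cluster_size)) return(FALSE)
      mus <- vapply(parts, function(v) mean(v), numeric(1))
      if (any(diff(mus) < cfg$min_separation_bp)) return(FALSE)
    }
    TRUE
  }
  crit_of <- function(parts) {
    sum(vapply(parts, function(v) blk(v)$ll, numeric(1))) -
      length(parts) * log(n)
  }
  best <- list(crit = crit_of(list(xs)), k = 1L, cuts = integer())
  for (c1 in seq_len(max(n - 1L, 0L))) {
    parts <- list(xs[1:c1], xs[(c1 + 1L):n])
    if (!feasible(parts)) next
    cr <- crit_of(parts)
    if (cr > best$crit + 1e-9) best <- list(crit = cr, k = 2L, cuts = c1)
  }
  if (n >= 3L) {
    for (c1 in seq_len(n - 2L)) for (c2 in seq.int(c1 + 1L, n - 1L)) {
      parts <- list(xs[1:c1], xs[(c1 + 1L):c2], xs[(c2 + 1L):n])
      if (!feasible(parts)) next
      cr <- crit_of(parts)
      if (cr > best$crit + 1e-9) best <- list(crit = cr, k = 3L, cuts = c(c1, c2))
    }
  }
  best
}

# --- haplotype map by literal segment concatenation ------------------------
# single-chromosome SV sets only (deletion / insertion / inversion /
# duplication); returns sorted label positions
oracle_apply_svs <- function(ref_map, svs) {
  pos <- ref_map$positions
  evs <- svs[order(vapply(svs, function(e) e$start_bp, numeric(1)))]
  pieces <- list()
  cursor <- 0 # reference coordinate already emitted
  out <- numeric()
  offset <- 0 # output position of `cursor`
  emit_ref <- function(from, to) { # labels of ref (from, to]
    p <- pos[pos > from & pos <= to]
    out <<- c(out, p - from + offset)
    offset <<- offset + (to - from)
    cursor <<- to
  }
  for (e in evs) {
    emit_ref(cursor, e$start_bp)
    if (e$sv_type == "deletion") {
      cursor <- e$end_bp
    } else if (e$sv_type == "insertion") {
      out <- c(out, offset + e$novel_offsets)
      offset <- offset + e$size_bp
    } else if (e$sv_type == "inversion") {
      p <- pos[pos > e$start_bp & pos <= e$end_bp]
      out <- c(out, offset + sort(e$end_bp - p))
      offset <- offset + (e$end_bp - e$start_bp)
      cursor <- e$end_bp
    } else if (e$sv_type == "duplication") {
      p <- pos[pos > e$start_bp & pos <= e$end_bp]
      emit_ref(cursor, e$end_bp)
      out <- c(out, offset + (p - e$start_bp))
      offset <- offset + (e$end_bp - e$start_bp)
    } else stop("oracle only handles local SV types")
  }
  emit_ref(cursor, ref_map$length_bp)
  sort(out[out > 0])
}

# --- optimal one-to-one assignment TP count --------------------------------
oracle_max_matching <- function(ok) { # ok: logical matrix calls x truth
  nc <- nrow(ok); nt <- ncol(ok)
  best <- 0L
  rec <- function(i, used_t, count) {
    if (count + (nc - i + 1L) <= best) return()
    if (i > nc) { best <<- max(best, count); return() }
    rec(i + 1L, used_t, count)
    for (j in seq_len(nt)) {
      if (!used_t[j] && ok[i, j]) {
        used_t[j] <- TRUE
        rec(i + 1L, used_t, count + 1L)
        used_t[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nt), 0L)
  best
}

# --- union-find over candidate intervals -----------------------------------
oracle_region_partition <- function(lefts, rights) {
  n <- length(lefts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && lefts[i] <= rights[j] && lefts[j] <= rights[i]) {
      parent[find(j)] <- find(i)
    }
  }
  vapply(seq_len(n), find, integer(1))
}
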