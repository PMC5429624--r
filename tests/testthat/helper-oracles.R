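# Independent oracles and fixture builders used across the test files.

# --- geometry ------------------------------------------------------------------

# torsion angle by the acos + triple-product-sign formula (independent of the
# package's atan2 implementation)
oracle_torsion <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-8 || sqrt(sum(n2^2)) < 1e-8) return(NA_real_)
  cosang <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# NeRF atom placement: position of D given A-B-C, bond length |CD|, bond angle
# B-C-D (degrees) and torsion A-B-C-D (degrees)
nerf_place <- function(A, B, C, length, angle, torsion) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  unit <- function(v) v / sqrt(sum(v^2))
  th <- angle * pi / 180; ph <- torsion * pi / 180
  bc <- unit(C - B)
  n <- unit(cross(B - A, bc))
  m <- cross(n, bc)
  d <- length * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Build an ideal polypeptide backbone (N, CA, C per residue) with prescribed
# phi/psi series (omega fixed at 180). Returns a protein chain list compatible
# with compute_dihedrals().
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7
  atoms <- vector("list", n)
  N <- c(0, 0, 0); CA <- c(b_NCA, 0, 0)
  C <- nerf_place(c(-1, 1, 0), N, CA, b_CAC, a_NCAC, 45)
  for (k in seq_len(n)) {
    if (k > 1) {
      # place this residue's N (psi of k-1), CA (omega), C (phi of k)
      N <- nerf_place(atoms[[k - 1]]["N", ], atoms[[k - 1]]["CA", ],
                      atoms[[k - 1]]["C", ], b_CN, a_CACN, psi[k - 1])
      CA <- nerf_place(atoms[[k - 1]]["CA", ], atoms[[k - 1]]["C", ], N,
                       b_NCA, a_CNCA, 180)
      C <- nerf_place(atoms[[k - 1]]["C", ], N, CA, b_CAC, a_NCAC, phi[k])
    }
    m <- rbind(N = N, CA = CA, C = C)
    attr(m, "element") <- c("N", "C", "C")
    atoms[[k]] <- m
  }
  list(chain_id = "A", index = seq_len(n), name = rep("ALA", n),
       seq = rep("A", n), atoms = atoms)
}

# --- local conformations -------------------------------------------------------

# exhaustive minimum-RMSDA protein-block assignment, written with plain loops
oracle_plc <- function(phi, psi, prototypes = plc_prototypes()) {
  n <- length(phi)
  out <- rep("Z", n)
  if (n < 5) return(paste(out, collapse = ""))
  for (i in 3:(n - 2)) {
    w <- c(psi[i - 2], phi[i - 1], psi[i - 1], phi[i],
           psi[i], phi[i + 1], psi[i + 1], phi[i + 2])
    if (anyNA(w)) next
    best <- Inf; best_letter <- "Z"
    for (r in seq_len(nrow(prototypes))) {
      ss <- 0
      for (a in 1:8) {
        d <- abs(w[a] - prototypes[r, a]) %% 360
        d <- min(d, 360 - d)
        ss <- ss + d^2
      }
      rmsda <- sqrt(ss / 8)
      if (rmsda < best) { best <- rmsda; best_letter <- rownames(prototypes)[r] }
    }
    out[i] <- best_letter
  }
  paste(out, collapse = "")
}

# random nested secondary structure of length n (recursive construction)
random_dot_bracket <- function(n, p_pair = 0.4) {
  if (n == 0) return("")
  if (n >= 4 && runif(1) < p_pair) {
    inner <- sample(0:(n - 2), 1)
    paste0("(", random_dot_bracket(inner, p_pair), ")",
           random_dot_bracket(n - 2 - inner, p_pair))
  } else {
    paste0(".", random_dot_bracket(n - 1, p_pair))
  }
}

# pair list from a dot-bracket (independent stack walk)
pairs_from_db <- function(db) {
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0)
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") {
      out <- rbind(out, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  out
}

# --- interfaces ----------------------------------------------------------------

# all-pairs brute-force contact scan
oracle_contacts <- function(complex, cutoff) {
  out <- matrix(numeric(0), ncol = 3)
  for (i in seq_along(complex$protein$atoms)) {
    for (j in seq_along(complex$rna$atoms)) {
      dmin <- Inf
      pa <- complex$protein$atoms[[i]]; ra <- complex$rna$atoms[[j]]
      for (a in seq_len(nrow(pa))) for (b in seq_len(nrow(ra)))
        dmin <- min(dmin, sqrt(sum((pa[a, ] - ra[b, ])^2)))
      if (dmin <= cutoff) out <- rbind(out, c(i, j, dmin))
    }
  }
  out
}

# a random two-chain complex with clustered atoms (no PDB involved)
random_complex <- function(n_res, n_nt, spread = 12, seed = 1) {
  set.seed(seed)
  mk_chain <- function(n, atom_names, elements, offset) {
    atoms <- lapply(seq_len(n), function(k) {
      c0 <- runif(3, 0, spread) + offset
      m <- sweep(matrix(rnorm(length(atom_names) * 3, sd = 0.8), ncol = 3),
                 2, c0, `+`)
      rownames(m) <- atom_names
      attr(m, "element") <- elements
      m
    })
    atoms
  }
  rpi_complex(
    protein = list(chain_id = "A", index = seq_len(n_res),
                   name = rep("ALA", n_res), seq = rep("A", n_res),
                   auth = as.character(seq_len(n_res)),
                   atoms = mk_chain(n_res, c("N", "CA", "C", "CB"),
                                    c("N", "C", "C", "C"), 0),
                   phi = rep(NA_real_, n_res), psi = rep(NA_real_, n_res)),
    rna = list(chain_id = "B", index = seq_len(n_nt),
               name = rep("A", n_nt), seq = rep("A", n_nt),
               auth = as.character(seq_len(n_nt)),
               atoms = mk_chain(n_nt, c("P", "C1'", "N1"),
                                c("P", "C", "N"), c(spread / 2, 0, 0))),
    source_id = paste0("random", seed)
  )
}

# --- metrics -------------------------------------------------------------------

# O(n^2) concordant-pair AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# write a toy PDB to a temp file and read it back
read_toy <- function(n_res, n_nt, contacts = NULL, seed = 1) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(generate_toy_pdb(n_res, n_nt, contacts, seed), tf)
  read_complex(tf, "A", "B")
}
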