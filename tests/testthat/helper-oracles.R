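# Independent oracles, re-implemented from first principles so they share no
# code path with the package functions they check.

# --- global alignment identity (Gotoh affine-gap DP with traceback) --------
gotoh_identity <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  gp <- function(L) gap_open + gap_ext * L
  for (i in 2:(n + 1)) { X[i, 1] <- -gp(i - 1); }
  for (j in 2:(m + 1)) { Y[1, j] <- -gp(j - 1); }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[A[i - 1], B[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - gp(1), X[i - 1, j] - gap_ext)
    Y[i, j] <- max(M[i, j - 1] - gp(1), Y[i, j - 1] - gap_ext)
  }
  # traceback from best terminal state
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  ident <- 0L
  while (i > 1 || j > 1) {
    if (state == 1) {
      if (A[i - 1] == B[j - 1] && A[i - 1] != "X") ident <- ident + 1L
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      up <- c(M[i - 1, j] - gp(1), X[i - 1, j] - gap_ext)
      state <- if (which.max(up) == 1) 1 else 2
      i <- i - 1
    } else {
      left <- c(M[i, j - 1] - gp(1), Y[i, j - 1] - gap_ext)
      state <- if (which.max(left) == 1) 1 else 3
      j <- j - 1
    }
  }
  ident / min(n, m)
}

# --- greedy clustering from an exhaustive identity matrix -------------------
greedy_cluster_oracle <- function(seqs, cutoff = 0.90) {
  ids <- names(seqs)
  n <- length(ids)
  idm <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    idm[i, j] <- pairwise_identity(seqs[[i]], seqs[[j]])
  ord <- ids[order(-nchar(seqs), ids)]
  reps <- character(); assign <- character(0)
  for (id in ord) {
    hit <- reps[idm[id, reps] > cutoff]
    if (length(hit) > 0) assign[id] <- hit[1]
    else { reps <- c(reps, id); assign[id] <- id }
  }
  list(representatives = reps, assign = assign)
}

# --- high-resolution SASA quadrature ---------------------------------------
# Independent numeric integration: a deterministic latitude-band point grid
# (not the golden spiral), all-pairs occlusion test.
sasa_quadrature <- function(atom, probe = 1.4, n_points = 10000) {
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  radii <- unname(vdw[atom$elesy]) + probe
  radii[is.na(radii)] <- 1.70 + probe
  # lat-long grid with area weights
  n_lat <- floor(sqrt(n_points / 2))
  n_lon <- 2 * n_lat
  theta <- (seq_len(n_lat) - 0.5) * pi / n_lat
  phi <- (seq_len(n_lon) - 0.5) * 2 * pi / n_lon
  grid <- expand.grid(theta = theta, phi = phi)
  pts <- cbind(sin(grid$theta) * cos(grid$phi),
               sin(grid$theta) * sin(grid$phi),
               cos(grid$theta))
  w <- sin(grid$theta)                   # area element weight
  w <- w / sum(w)
  xyz <- cbind(atom$x, atom$y, atom$z)
  vapply(seq_len(nrow(atom)), function(i) {
    p <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(p))
    for (j in seq_len(nrow(atom))) {
      if (j == i) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > radii[j]^2
    }
    4 * pi * radii[i]^2 * sum(w[exposed])
  }, 0)
}

# --- brute-force contact enumerations --------------------------------------
atom_dist <- function(atom, i, j) {
  sqrt((atom$x[i] - atom$x[j])^2 + (atom$y[i] - atom$y[j])^2 +
         (atom$z[i] - atom$z[j])^2)
}

# unique residue pairs with any cross-selection atom pair of the given atom
# sets within cutoff (loops over all pairs, no neighbour tricks)
brute_residue_pairs <- function(atom, ia, ib, cutoff) {
  out <- character()
  for (i in ia) for (j in ib) {
    ra <- paste(atom$chain[i], atom$resno[i], sep = ":")
    rb <- paste(atom$chain[j], atom$resno[j], sep = ":")
    if (ra == rb) next
    if (atom_dist(atom, i, j) <= cutoff)
      out <- c(out, paste(min(ra, rb), max(ra, rb)))
  }
  sort(unique(out))
}

interaction_pair_keys <- function(ints) {
  if (nrow(ints) == 0) return(character())
  ra <- paste(ints$chain_a, ints$resno_a, sep = ":")
  rb <- paste(ints$chain_b, ints$resno_b, sep = ":")
  sort(unique(paste(pmin(ra, rb), pmax(ra, rb))))
}

# H-bond-capable atom indices, tabulated independently of the package
brute_hb_atoms <- function(atom, role) {
  don <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
              HIS = c("ND1", "NE2"), LYS = "NZ",
              ARG = c("NE", "NH1", "NH2"), TRP = "NE1")
  acc <- list(SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
              ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
              HIS = c("ND1", "NE2"))
  which(vapply(seq_len(nrow(atom)), function(i) {
    if (atom$het[i]) return(FALSE)
    if (role == "donor") {
      atom$elety[i] == "N" && atom$resid[i] != "PRO" ||
        atom$elety[i] %in% (don[[atom$resid[i]]] %||% character())
    } else {
      atom$elety[i] %in% c("O", "OXT") ||
        atom$elety[i] %in% (acc[[atom$resid[i]]] %||% character())
    }
  }, TRUE))
}

brute_hbond_pairs <- function(atom, cutoff = 3.5) {
  don <- brute_hb_atoms(atom, "donor")
  acc <- brute_hb_atoms(atom, "acceptor")
  out <- character()
  for (i in don) for (j in acc) {
    ra <- paste(atom$chain[i], atom$resno[i], sep = ":")
    rb <- paste(atom$chain[j], atom$resno[j], sep = ":")
    if (ra == rb) next
    bb <- c("N", "CA", "C", "O", "OXT")
    if (atom$elety[i] %in% bb && atom$elety[j] %in% bb &&
        atom$chain[i] == atom$chain[j] &&
        abs(atom$resno[i] - atom$resno[j]) < 2) next
    if (atom_dist(atom, i, j) <= cutoff)
      out <- c(out, paste(min(ra, rb), max(ra, rb)))
  }
  sort(unique(out))
}

brute_water_bridges <- function(atom, cutoff = 3.5) {
  prot <- which(!atom$het & atom$elesy %in% c("N", "O"))
  wat <- which(atom$resid %in% c("HOH", "WAT", "DOD") & atom$elety == "O")
  lig <- which(atom$het & !atom$resid %in% c("HOH", "WAT", "DOD") &
                 atom$elesy %in% c("O", "P"))
  out <- character()
  for (w in wat) for (p in prot) for (l in lig) {
    if (atom_dist(atom, p, w) <= cutoff && atom_dist(atom, w, l) <= cutoff)
      out <- c(out, paste(atom$chain[p], atom$resno[p], atom$resno[w]))
  }
  sort(unique(out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
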