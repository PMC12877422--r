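# Independent reference implementations used only by the tests.
# These deliberately share no code with the package: alignment scores come
# from a plain-R Gotoh dynamic program, partition metrics from literal
# pair counting / entropy sums, and FASTA parsing from naive line
# concatenation.

oracle_matrix <- function() cazyclust::default_substitution_matrix()

# Affine-gap DP (Gotoh) for global (terminal gaps penalized) and local
# (Smith-Waterman) alignment.  Returns the optimal score, the number of
# optimal alignments (capped at 2), and - when the optimum is unique - the
# matches / aligned-column / query-residue counts of that alignment.
oracle_align <- function(a, b, type = c("global", "local"),
                         open = 11, ext = 1, mat = oracle_matrix()) {
  type <- match.arg(type)
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  NEG <- -1e9
  sub <- matrix(0, n, m)
  for (i in seq_len(n)) sub[i, ] <- mat[x[i], y]

  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  CM <- CIx <- CIy <- matrix(0, n + 1, m + 1)
  M[1, 1] <- 0
  CM[1, 1] <- 1
  if (type == "global") {
    for (i in seq_len(n)) {
      Ix[i + 1, 1] <- -(open + ext * i)
      CIx[i + 1, 1] <- 1
    }
    for (j in seq_len(m)) {
      Iy[1, j + 1] <- -(open + ext * j)
      CIy[1, j + 1] <- 1
    }
  }
  cap <- function(k) min(k, 2)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      # M: x_i aligned to y_j
      cands <- c(M[i, j], Ix[i, j], Iy[i, j])
      if (type == "local") cands <- c(cands, 0)
      best <- max(cands)
      M[i + 1, j + 1] <- best + sub[i, j]
      cnt <- 0
      if (M[i, j] == best) cnt <- cnt + CM[i, j]
      if (Ix[i, j] == best) cnt <- cnt + CIx[i, j]
      if (Iy[i, j] == best) cnt <- cnt + CIy[i, j]
      if (type == "local" && best == 0) cnt <- cnt + 1
      CM[i + 1, j + 1] <- cap(cnt)
      # Ix: x_i aligned to a gap
      o1 <- M[i, j + 1] - open - ext
      o2 <- Ix[i, j + 1] - ext
      Ix[i + 1, j + 1] <- max(o1, o2)
      cnt <- 0
      if (o1 == Ix[i + 1, j + 1]) cnt <- cnt + CM[i, j + 1]
      if (o2 == Ix[i + 1, j + 1]) cnt <- cnt + CIx[i, j + 1]
      CIx[i + 1, j + 1] <- cap(cnt)
      # Iy: y_j aligned to a gap
      o1 <- M[i + 1, j] - open - ext
      o2 <- Iy[i + 1, j] - ext
      Iy[i + 1, j + 1] <- max(o1, o2)
      cnt <- 0
      if (o1 == Iy[i + 1, j + 1]) cnt <- cnt + CM[i + 1, j]
      if (o2 == Iy[i + 1, j + 1]) cnt <- cnt + CIy[i + 1, j]
      CIy[i + 1, j + 1] <- cap(cnt)
    }
  }

  if (type == "global") {
    score <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
    n_opt <- 0
    ends <- list()
    for (st in c("M", "Ix", "Iy")) {
      v <- switch(st, M = M, Ix = Ix, Iy = Iy)[n + 1, m + 1]
      if (v == score) {
        n_opt <- n_opt + switch(st, M = CM, Ix = CIx, Iy = CIy)[n + 1, m + 1]
        ends[[length(ends) + 1]] <- list(i = n, j = m, st = st)
      }
    }
  } else {
    score <- max(0, M)
    ends <- list()
    n_opt <- 0
    if (score == 0) {
      n_opt <- 1 # the empty alignment
    } else {
      for (i in seq_len(n)) {
        for (j in seq_len(m)) {
          if (M[i + 1, j + 1] == score) {
            n_opt <- n_opt + CM[i + 1, j + 1]
            ends[[length(ends) + 1]] <- list(i = i, j = j, st = "M")
          }
        }
      }
    }
  }
  n_opt <- cap(n_opt)

  out <- list(score = score, n_opt = n_opt)
  if (n_opt != 1) {
    return(out)
  }
  if (type == "local" && score == 0) {
    out$matches <- 0L
    out$aligned_columns <- 0L
    out$query_residues <- 0L
    return(out)
  }

  # unique optimum: trace it back and tally matches / columns inside the
  # span between the first and last aligned residue pair.  Uniqueness means
  # exactly one predecessor option is consistent at every step.
  e <- ends[[1]]
  i <- e$i
  j <- e$j
  st <- e$st
  cols <- list() # each entry: c(xi, yj) with 0 for gap
  repeat {
    if (i == 0 && j == 0) break
    if (st == "M") {
      cols[[length(cols) + 1]] <- c(i, j)
      tgt <- M[i + 1, j + 1] - sub[i, j]
      if (type == "local" && tgt == 0 &&
        !(M[i, j] == tgt && CM[i, j] > 0) &&
        !(Ix[i, j] == tgt && CIx[i, j] > 0) &&
        !(Iy[i, j] == tgt && CIy[i, j] > 0)) {
        break # local alignment starts here
      }
      if (i == 1 && j == 1 && type == "global") {
        break # reached M[0,0]
      }
      if (M[i, j] == tgt && CM[i, j] > 0) {
        st <- "M"
      } else if (Ix[i, j] == tgt && CIx[i, j] > 0) {
        st <- "Ix"
      } else if (Iy[i, j] == tgt && CIy[i, j] > 0) {
        st <- "Iy"
      } else {
        stop("oracle traceback failed (M)")
      }
      i <- i - 1
      j <- j - 1
    } else if (st == "Ix") {
      cols[[length(cols) + 1]] <- c(i, 0)
      if (j == 0) { # global boundary column: all-gap prefix
        i <- i - 1
        if (i == 0) break
        next
      }
      val <- Ix[i + 1, j + 1]
      if (M[i, j + 1] == val + open + ext && CM[i, j + 1] > 0) {
        st <- "M"
      } else if (Ix[i, j + 1] == val + ext && CIx[i, j + 1] > 0) {
        st <- "Ix"
      } else {
        stop("oracle traceback failed (Ix)")
      }
      i <- i - 1
    } else {
      cols[[length(cols) + 1]] <- c(0, j)
      if (i == 0) { # global boundary row: all-gap prefix
        j <- j - 1
        if (j == 0) break
        next
      }
      val <- Iy[i + 1, j + 1]
      if (M[i + 1, j] == val + open + ext && CM[i + 1, j] > 0) {
        st <- "M"
      } else if (Iy[i + 1, j] == val + ext && CIy[i + 1, j] > 0) {
        st <- "Iy"
      } else {
        stop("oracle traceback failed (Iy)")
      }
      j <- j - 1
    }
  }
  colm <- do.call(rbind, rev(cols))
  aligned <- colm[, 1] > 0 & colm[, 2] > 0
  spn <- range(which(aligned))
  idx <- spn[1]:spn[2]
  out$matches <- sum(aligned[idx] & x[pmax(colm[idx, 1], 1)] == y[pmax(colm[idx, 2], 1)] &
    colm[idx, 1] > 0 & colm[idx, 2] > 0)
  out$aligned_columns <- length(idx)
  out$query_residues <- sum(colm[idx, 1] > 0)
  out
}

# ARI by literal pair counting over all C(n,2) pairs.
oracle_ari <- function(x, y) {
  n <- length(x)
  sx <- outer(x, x, "==")[upper.tri(diag(n))]
  sy <- outer(y, y, "==")[upper.tri(diag(n))]
  n11 <- sum(sx & sy)
  n10 <- sum(sx & !sy)
  n01 <- sum(!sx & sy)
  n00 <- sum(!sx & !sy)
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) {
    return(if (n10 + n01 == 0) 1 else 0)
  }
  2 * (n11 * n00 - n10 * n01) / denom
}

# NMI (arithmetic normalization) from explicit probability sums.
oracle_nmi <- function(x, y) {
  n <- length(x)
  ux <- unique(x)
  uy <- unique(y)
  mi <- 0
  for (a in ux) {
    for (b in uy) {
      pab <- sum(x == a & y == b) / n
      if (pab > 0) {
        mi <- mi + pab * log(pab / (sum(x == a) / n * sum(y == b) / n))
      }
    }
  }
  hx <- -sum(vapply(ux, function(a) {
    p <- sum(x == a) / n
    p * log(p)
  }, 0))
  hy <- -sum(vapply(uy, function(b) {
    p <- sum(y == b) / n
    p * log(p)
  }, 0))
  if (hx == 0 && hy == 0) {
    return(if (length(unique(paste(x, y))) == max(length(ux), length(uy))) 1 else 0)
  }
  max(0, min(1, mi / ((hx + hy) / 2)))
}

# All set partitions of n elements, as integer label vectors in
# first-occurrence canonical form.
all_partitions <- function(n) {
  if (n == 0) {
    return(list())
  }
  parts <- list(c(1L))
  for (el in seq_len(n - 1)) {
    nxt <- list()
    for (p in parts) {
      k <- max(p)
      for (lab in seq_len(k + 1)) {
        nxt[[length(nxt) + 1]] <- c(p, lab)
      }
    }
    parts <- nxt
  }
  parts
}

# Naive FASTA reader: concatenate lines until the next header.
naive_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  ids <- sub("^>(\\S+).*", "\\1", lines[hdr])
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[(hdr[i] + 1):ends[i]], collapse = "")
  }, "")
  setNames(seqs, ids)
}

rand_seq <- function(len) {
  paste(sample(c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  ), len, replace = TRUE), collapse = "")
}
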