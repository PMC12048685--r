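# Independent brute-force oracles used to validate the fast implementations.

# Per-pixel local median/MAD threshold + hand flood fill, written the
# straightforward way with explicit loops. Returns spot masks as sorted
# integer key vectors (row * 2^15 + col, 0-based) plus areas.
oracle_detect <- function(img, window = 15, k = 5, min_area = 2,
                          max_area = 200) {
  nr <- nrow(img); nc <- ncol(img)
  h <- window %/% 2
  fg <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r0 <- max(1, i - h); r1 <- min(nr, i + h)
      c0 <- max(1, j - h); c1 <- min(nc, j + h)
      vals <- as.vector(img[r0:r1, c0:c1])
      med <- median(vals)
      madv <- median(abs(vals - med))
      fg[i, j] <- img[i, j] > med + k * madv
    }
  }
  seen <- matrix(FALSE, nr, nc)
  masks <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!fg[i, j] || seen[i, j]) next
      stack <- list(c(i, j))
      seen[i, j] <- TRUE
      px <- matrix(integer(0), ncol = 2)
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        px <- rbind(px, p)
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (fg[rr, cc] && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            stack[[length(stack) + 1]] <- c(rr, cc)
          }
        }
      }
      if (nrow(px) >= min_area && nrow(px) <= max_area) {
        masks[[length(masks) + 1]] <-
          unname(sort((px[, 1] - 1) * 2^15 + (px[, 2] - 1)))
      }
    }
  }
  masks
}

# Canonical representation of detect_spots() masks for set comparison.
spot_mask_keys <- function(spots) {
  keys <- lapply(spots$mask, function(m) sort(m[, 1] * 2^15 + m[, 2]))
  keys[order(vapply(keys, min, numeric(1)))]
}

oracle_mask_keys <- function(masks) {
  if (length(masks) == 0) return(list())
  masks[order(vapply(masks, min, numeric(1)))]
}

# Hand-rolled reverse complement, independent of Biostrings.
oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

# Codon-walk uAUG oracle: walk codon starts forward from each ATG; the
# uAUG is in-frame iff the walk lands exactly on the main start (one base
# past the UTR end); a uORF needs a stop codon fully inside the UTR on
# that walk.
oracle_uaugs <- function(utr) {
  n <- nchar(utr)
  res <- data.frame(offset = integer(0), frame = integer(0),
                    is_uorf = logical(0))
  for (off in 0:(n - 3)) {
    if (substr(utr, off + 1, off + 3) != "ATG") next
    # frame: walk codon starts from the ATG; the leftover bases before the
    # main start are the frame shift (0 = lands exactly on the main AUG).
    p <- off
    stopped <- FALSE
    while (p + 3 <= n) {
      codon <- substr(utr, p + 1, p + 3)
      if (p > off && !stopped && codon %in% c("TAA", "TAG", "TGA")) {
        stopped <- TRUE
      }
      p <- p + 3
    }
    res <- rbind(res, data.frame(offset = off, frame = (n - p) %% 3L,
                                 is_uorf = stopped))
  }
  res
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
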