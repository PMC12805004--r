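# Independent oracles used across the suite. These deliberately avoid the
# package's own enumeration/counting code paths.

# All set partitions of n elements as canonical label vectors, by direct
# recursive element placement (independent of symcat's restricted-growth
# enumerator, which extends strings positionally with a block cap).
oracle_set_partitions <- function(n) {
  parts <- list(list(1L))  # partition of {1}: one block holding element 1
  if (n >= 2) {
    for (el in 2:n) {
      nxt <- list()
      for (p in parts) {
        for (b in seq_along(p)) {
          q <- p
          q[[b]] <- c(q[[b]], el)
          nxt[[length(nxt) + 1L]] <- q
        }
        nxt[[length(nxt) + 1L]] <- c(p, list(el))
      }
      parts <- nxt
    }
  }
  lapply(parts, function(p) {
    a <- integer(n)
    for (b in seq_along(p)) a[p[[b]]] <- b
    match(a, unique(a))  # canonical first-occurrence labels
  })
}

# Is every block of the assignment connected in the given adjacency
# (edge list of 0-based pairs)? Brute force by repeated edge contraction.
oracle_blocks_connected <- function(assignment, edges) {
  if (nrow(edges) == 0) return(TRUE)
  for (b in unique(assignment)) {
    pts <- which(assignment == b) - 1L
    if (length(pts) == 1L) next
    comp <- as.list(pts)
    repeat {
      merged <- FALSE
      for (r in seq_len(nrow(edges))) {
        i <- edges[r, 1]; j <- edges[r, 2]
        ci <- which(vapply(comp, function(cc) i %in% cc, logical(1)))
        cj <- which(vapply(comp, function(cc) j %in% cc, logical(1)))
        if (length(ci) == 1 && length(cj) == 1 && ci != cj) {
          comp[[ci]] <- c(comp[[ci]], comp[[cj]])
          comp <- comp[-cj]
          merged <- TRUE
          break
        }
      }
      if (!merged || length(comp) == 1L) break
    }
    if (length(comp) > 1L) return(FALSE)
  }
  TRUE
}

# Connected partitions of a structure by filtering all set partitions
# (feasible for n <= 9).
oracle_connected_partitions <- function(struct) {
  n <- nrow(struct$space$points)
  edges <- struct$space$adjacency
  keep <- Filter(function(a) oracle_blocks_connected(a, edges),
                 oracle_set_partitions(n))
  keep
}

# Compositions of n (ordered tuples of positive parts), as lists.
oracle_compositions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (first in seq_len(n)) {
    if (first == n) {
      out[[length(out) + 1L]] <- n
    } else {
      for (rest in oracle_compositions(n - first)) {
        out[[length(out) + 1L]] <- c(first, rest)
      }
    }
  }
  out
}

oracle_palindromic_compositions <- function(n) {
  Filter(function(cmp) identical(cmp, rev(cmp)), oracle_compositions(n))
}

# Convenience: sizes of a list of category systems.
system_sizes <- function(systems) {
  sort(vapply(systems, function(s) s$size, integer(1)))
}

# Manual per-glottocode record selection mirroring the conservative
# dedupe rule, written independently (loops, no dplyr grouping).
oracle_dedupe <- function(records, predicted_parity) {
  records$parity <- ifelse(records$size %% 2 == 0, "even", "odd")
  no_code <- is.na(records$glottocode) | records$glottocode == ""
  keep_idx <- which(no_code)
  for (gc in unique(records$glottocode[!no_code])) {
    idx <- which(!no_code & records$glottocode == gc)
    if (length(idx) == 1L || length(unique(records$parity[idx])) == 1L) {
      keep_idx <- c(keep_idx, idx[1])
    } else if (predicted_parity == "none") {
      keep_idx <- c(keep_idx, idx[1])
    } else {
      contra <- if (predicted_parity == "even") "odd" else "even"
      keep_idx <- c(keep_idx, idx[records$parity[idx] == contra][1])
    }
  }
  records[sort(keep_idx), , drop = FALSE]
}

# A small English-like sibling term table: brother/sister over the full
# 12-type inventory.
english_sibling_table <- function() {
  tibble::tibble(
    language = "English",
    glottocode = "stan1293",
    term = rep(c("brother", "sister"), each = 6),
    kin_type = c("mB", "meB", "myB", "fB", "feB", "fyB",
                 "mZ", "meZ", "myZ", "fZ", "feZ", "fyZ")
  )
}
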