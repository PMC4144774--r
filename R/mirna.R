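# miRNA target and target-mimic (eTM) scanning over lincRNA sequences.
#
# Pure pairing-pattern rules (no free-energy model).  Internally everything
# is in the DNA alphabet; T is read as U.  A miRNA position j (5'->3') pairs
# antiparallel with window position w+1-j, so a target window is an
# approximate match of the reverse complement of the miRNA:
#   Watson–Crick match  : window base equals revcomp(miRNA) base
#   G:U wobble          : miRNA G against window T, or miRNA U against
#                         window G (i.e. revcomp base C against T, A vs G)
#   anything else       : mismatch (N always mismatches)
# Targets: mismatches + G:U wobbles <= 3 over the full miRNA, no bulge.
# Mimics: perfect Watson–Crick pairing at miRNA positions 2-8, a bulge of
# exactly 3 lincRNA nucleotides opposite miRNA positions 9-11, and at most 3
# mismatches + G:U elsewhere; a site that also satisfies the stricter target
# rule is reported only as a target.  All rule constants are configurable.

#' Pairing rules for target and mimic scanning
#'
#' @param max_mismatch_plus_gu combined mismatch + G:U budget for targets.
#' @param mimic_seed_range miRNA positions (inclusive range) that must pair
#'   perfectly for a mimic.
#' @param mimic_bulge_positions miRNA positions (inclusive range) opposite
#'   which the lincRNA bulge must sit: the insertion point between miRNA
#'   positions p and p+1 is allowed when both p and p+1 are inside the range.
#' @param mimic_bulge_length required bulge length in lincRNA nucleotides.
#' @param mimic_max_other_mm_gu mismatch + G:U budget outside the seed for
#'   mimics.
#' @return list of class `pairing_rules`.
#' @export
pairing_rules <- function(max_mismatch_plus_gu = 3L,
                          mimic_seed_range = c(2L, 8L),
                          mimic_bulge_positions = c(9L, 11L),
                          mimic_bulge_length = 3L,
                          mimic_max_other_mm_gu = 3L) {
  structure(list(max_mismatch_plus_gu = max_mismatch_plus_gu,
                 mimic_seed_range = mimic_seed_range,
                 mimic_bulge_positions = mimic_bulge_positions,
                 mimic_bulge_length = mimic_bulge_length,
                 mimic_max_other_mm_gu = mimic_max_other_mm_gu),
            class = "pairing_rules")
}

# per-position pairing class of window chars W against miRNA chars M
# (antiparallel, j-th miRNA base vs wpos(j)-th window base); returns a
# character vector over miRNA positions: "|" match, ":" wobble, "." mismatch
pair_class <- function(mirna_chars, window_chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  wc <- window_chars == comp[mirna_chars]
  gu <- (mirna_chars == "G" & window_chars == "T") |
        (mirna_chars == "T" & window_chars == "G")
  out <- rep(".", length(mirna_chars))
  out[gu] <- ":"
  out[wc] <- "|"
  out
}

check_mirna <- function(mirna) {
  m <- toupper(chartr("U", "T", as.character(mirna)))
  if (grepl("[^ACGT]", m)) stop("degenerate base in miRNA sequence")
  m
}

# vectorised window scan of one strand; returns data.table of windows with
# mm+gu counts and pairing strings
scan_strand_targets <- function(mirna_chars, seq_chars, limit) {
  m <- length(mirna_chars)
  L <- length(seq_chars)
  if (L < m) return(data.table(start = integer(0)))
  n_win <- L - m + 1L
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  mm_gu <- integer(n_win)
  is_gu <- matrix(FALSE, n_win, m)
  is_wc <- matrix(FALSE, n_win, m)
  for (j in seq_len(m)) {
    wpos <- m + 1L - j            # offset within window for miRNA position j
    b <- seq_chars[wpos:(wpos + n_win - 1L)]
    wc <- b == comp[[mirna_chars[j]]]
    gu <- (mirna_chars[j] == "G" & b == "T") | (mirna_chars[j] == "T" & b == "G")
    is_wc[, j] <- wc
    is_gu[, j] <- gu & !wc
    mm_gu <- mm_gu + as.integer(!wc)
  }
  hit <- which(mm_gu <= limit)
  if (!length(hit)) return(data.table(start = integer(0)))
  pairing <- vapply(hit, function(i) {
    cls <- rep(".", m)
    cls[is_gu[i, ]] <- ":"
    cls[is_wc[i, ]] <- "|"
    # report 5'->3' along the window (miRNA position m .. 1)
    paste(rev(cls), collapse = "")
  }, character(1))
  data.table(start = hit, end = hit + m - 1L,
             mismatches = vapply(hit, function(i)
               sum(!is_wc[i, ] & !is_gu[i, ]), integer(1)),
             gu_pairs = vapply(hit, function(i) sum(is_gu[i, ]), integer(1)),
             pairing = pairing)
}

#' Scan a lincRNA for miRNA cleavage-target sites
#'
#' Both strands of the lincRNA are scanned with every window of miRNA
#' length aligned antiparallel to the miRNA; windows whose combined
#' mismatch + G:U count is within the budget (default 3) are reported.  No
#' bulges are allowed in target mode.
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet, 5'->3'); degenerate
#'   bases are an error.
#' @param linc_sequence lincRNA sequence (sense strand, DNA alphabet).
#' @param rules a [pairing_rules()].
#' @param mirna_id,linc_id identifiers for the report.
#' @return A `data.table` of interaction sites (`kind = "target"`): strand,
#'   window start/end in sense-strand coordinates, mismatch and G:U counts,
#'   and the pairing string (`|` match, `:` G:U, `.` mismatch, 5'->3' along
#'   the scanned strand).
#' @export
scan_targets <- function(mirna, linc_sequence, rules = pairing_rules(),
                         mirna_id = "mirna", linc_id = "linc") {
  m <- check_mirna(mirna)
  s <- toupper(as.character(linc_sequence))
  stopifnot(nchar(s) >= nchar(m))
  mirna_chars <- strsplit(m, "", fixed = TRUE)[[1]]
  L <- nchar(s)
  parts <- list()
  for (strand in c("+", "-")) {
    sc <- strsplit(if (strand == "+") s else revcomp(s), "", fixed = TRUE)[[1]]
    w <- scan_strand_targets(mirna_chars, sc, rules$max_mismatch_plus_gu)
    if (!nrow(w)) next
    if (strand == "-") {
      w[, c("start", "end") := list(L - end + 1L, L - start + 1L)]
    }
    w[, strand := strand]
    parts[[strand]] <- w
  }
  out <- rbindlist(parts)
  if (!nrow(out)) {
    return(data.table(mirna_id = character(0), linc_id = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      gu_pairs = integer(0), pairing = character(0),
                      bulge_start = integer(0), bulge_len = integer(0),
                      kind = character(0)))
  }
  out[, c("mirna_id", "linc_id", "kind") := list(mirna_id, linc_id, "target")]
  out[, c("bulge_start", "bulge_len") := list(NA_integer_, NA_integer_)]
  setorder(out, strand, start)
  out[, list(mirna_id, linc_id, strand, start, end, mismatches, gu_pairs,
             pairing, bulge_start, bulge_len, kind)]
}

#' Scan a lincRNA for miRNA target-mimic (eTM) sites
#'
#' Windows of miRNA length plus the bulge length are tested with the bulge
#' inserted between miRNA positions p and p+1 for every allowed insertion
#' point: perfect Watson–Crick pairing is required over the seed positions,
#' the bulge is left unpaired, and the remaining positions must stay within
#' the mismatch + G:U budget.  Sites that also satisfy the stricter
#' (bulge-free) target rule are reported only as targets and suppressed
#' here.
#'
#' @inheritParams scan_targets
#' @return A `data.table` of interaction sites (`kind = "mimic"`) with the
#'   bulge position (sense-strand coordinates) and length.
#' @export
scan_mimics <- function(mirna, linc_sequence, rules = pairing_rules(),
                        mirna_id = "mirna", linc_id = "linc") {
  m_str <- check_mirna(mirna)
  s <- toupper(as.character(linc_sequence))
  stopifnot(nchar(s) >= nchar(m_str))
  mc <- strsplit(m_str, "", fixed = TRUE)[[1]]
  m <- length(mc)
  b <- rules$mimic_bulge_length
  w_len <- m + b
  seed <- seq(rules$mimic_seed_range[1], rules$mimic_seed_range[2])
  ins_points <- seq(rules$mimic_bulge_positions[1],
                    rules$mimic_bulge_positions[2] - 1L)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  L <- nchar(s)
  targets <- scan_targets(m_str, s, rules, mirna_id, linc_id)
  parts <- list()
  for (strand in c("+", "-")) {
    sc <- strsplit(if (strand == "+") s else revcomp(s), "", fixed = TRUE)[[1]]
    if (length(sc) < w_len) next
    n_win <- length(sc) - w_len + 1L
    for (p in ins_points) {
      wpos <- ifelse(seq_len(m) <= p, w_len + 1L - seq_len(m),
                     w_len + 1L - seq_len(m) - b)
      wc <- matrix(FALSE, n_win, m)
      gu <- matrix(FALSE, n_win, m)
      for (j in seq_len(m)) {
        bb <- sc[wpos[j]:(wpos[j] + n_win - 1L)]
        wcj <- bb == comp[[mc[j]]]
        guj <- (mc[j] == "G" & bb == "T") | (mc[j] == "T" & bb == "G")
        wc[, j] <- wcj
        gu[, j] <- guj & !wcj
      }
      seed_ok <- rowSums(!wc[, seed, drop = FALSE]) == 0L
      other <- setdiff(seq_len(m), seed)
      budget <- rowSums(!wc[, other, drop = FALSE])
      hit <- which(seed_ok & budget <= rules$mimic_max_other_mm_gu)
      for (i in hit) {
        cls <- rep(".", m)
        cls[gu[i, ]] <- ":"
        cls[wc[i, ]] <- "|"
        # bulge occupies window offsets (w_len - p - b + 1) .. (w_len - p)
        bstart_local <- i + (w_len - p - b)
        st <- i; en <- i + w_len - 1L
        if (strand == "-") {
          st2 <- L - en + 1L; en2 <- L - st + 1L
          bstart <- L - (bstart_local + b - 1L) + 1L
          st <- st2; en <- en2
        } else {
          bstart <- bstart_local
        }
        parts[[length(parts) + 1L]] <- data.table(
          mirna_id = mirna_id, linc_id = linc_id, strand = strand,
          start = st, end = en,
          mismatches = sum(!wc[i, ] & !gu[i, ]) - 0L,
          gu_pairs = sum(gu[i, ]),
          pairing = paste(rev(c(cls[seq_len(p)], rep("b", b),
                                cls[(p + 1L):m])), collapse = ""),
          bulge_start = as.integer(bstart), bulge_len = as.integer(b),
          kind = "mimic")
      }
    }
  }
  out <- rbindlist(parts)
  if (!nrow(out)) {
    return(data.table(mirna_id = character(0), linc_id = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      gu_pairs = integer(0), pairing = character(0),
                      bulge_start = integer(0), bulge_len = integer(0),
                      kind = character(0)))
  }
  out <- unique(out, by = c("strand", "start", "end", "bulge_start"))
  # suppress sites that overlap a window already satisfying the target rule
  if (nrow(targets)) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      !any(targets$strand == out$strand[i] &
             targets$start <= out$end[i] & targets$end >= out$start[i])
    }, logical(1))
    out <- out[keep]
  }
  setorder(out, strand, start)
  out[]
}

#' Build a miRNA–lincRNA interaction network
#'
#' Collapses interaction sites to a bipartite edge list (one edge per
#' miRNA–lincRNA pair and role) and summarises per miRNA how many lincRNAs
#' it degrades (target role) and how many mimic it.
#'
#' @param target_sites,mimic_sites site tables from [scan_targets()] /
#'   [scan_mimics()] (rows from several scans may be concatenated).
#' @return A list: `edges` (`mirna_id`, `linc_id`,
#'   `role` in `degrades` / `mimicked_by`) and `summary` (per-miRNA counts).
#' @export
build_interaction_network <- function(target_sites, mimic_sites) {
  e1 <- if (!is.null(target_sites) && nrow(target_sites)) {
    unique(data.table(mirna_id = target_sites$mirna_id,
                      linc_id = target_sites$linc_id, role = "degrades"))
  } else data.table(mirna_id = character(0), linc_id = character(0),
                    role = character(0))
  e2 <- if (!is.null(mimic_sites) && nrow(mimic_sites)) {
    unique(data.table(mirna_id = mimic_sites$mirna_id,
                      linc_id = mimic_sites$linc_id, role = "mimicked_by"))
  } else data.table(mirna_id = character(0), linc_id = character(0),
                    role = character(0))
  edges <- rbind(e1, e2)
  if (nrow(edges)) {
    summary <- edges[, list(degrades = sum(role == "degrades"),
                            mimicked_by = sum(role == "mimicked_by")),
                     by = "mirna_id"]
  } else {
    summary <- data.table(mirna_id = character(0), degrades = integer(0),
                          mimicked_by = integer(0))
  }
  list(edges = edges, summary = summary)
}
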