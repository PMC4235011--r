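# Seed-match site classification of 3' UTRs, the seed-disruption mutation
# utility, and the degenerate TCF/beta-catenin motif scanner.
#
# Site taxonomy (decreasing efficacy / precedence):
#   8mer      : perfect match to miRNA nts 2-8 plus an A opposite nt 1
#   7mer-m8   : perfect match to miRNA nts 2-8
#   7mer-1A   : perfect match to miRNA nts 2-7 plus an A opposite nt 1
#   6mer-n2-7 : perfect match to miRNA nts 2-7
#   6mer-n3-8 : perfect match to miRNA nts 3-8
# All coordinates are 1-based inclusive on the sense strand of the UTR.

#' Seed-site types in precedence order
#'
#' The five canonical miRNA seed-match site classes, strongest first, plus
#' `"none"`. The order defines the precedence used by [classify_utr()] and
#' the expected recruitment-efficiency hierarchy tested by
#' [check_hierarchy()].
#'
#' @return Character vector of the six class labels.
#' @export
seed_site_types <- function() {
  c("8mer", "7mer-m8", "7mer-1A", "6mer-n2-7", "6mer-n3-8", "none")
}

#' Extract a region of a mature miRNA sequence
#'
#' 1-based inclusive slice of a mature miRNA given 5' to 3'. The canonical
#' seed region is nucleotides 2-7; the extended seed used by the 7mer-m8
#' and 8mer site types is nucleotides 2-8.
#'
#' @param mirna Mature miRNA sequence, 5' to 3' (RNA or DNA alphabet;
#'   T is read as U).
#' @param from_nt,to_nt 1-based inclusive nucleotide positions.
#' @return The requested subsequence in the RNA alphabet.
#' @examples
#' mirna_seed("UGAGGUAGUAGGUUGUAUAGUU", 2, 7)
#' @export
mirna_seed <- function(mirna, from_nt = 2, to_nt = 7) {
  mirna <- as_rna(mirna)
  if (from_nt < 1 || to_nt < from_nt || to_nt > nchar(mirna)) {
    stop("invalid-argument: seed coordinates out of range for a ",
         nchar(mirna), " nt miRNA")
  }
  substr(mirna, from_nt, to_nt)
}

# Reverse complement in the RNA alphabet, via Biostrings.
rna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

#' UTR match strings for each seed-site type
#'
#' Builds, for a mature miRNA, the exact mRNA (sense-strand) sequences whose
#' presence in a 3' UTR constitutes each seed-match site type. Match strings
#' are the reverse complements of the corresponding seed regions; the 8mer
#' and 7mer-1A types additionally require an A in the mRNA opposite miRNA
#' position 1 (appended 3' of the seed match).
#'
#' @inheritParams mirna_seed
#' @return Named character vector (RNA alphabet) over the five site types.
#' @examples
#' site_patterns("UGAGGUAGUAGGUUGUAUAGUU")
#' @export
site_patterns <- function(mirna) {
  mirna <- as_rna(mirna)
  if (nchar(mirna) < 8) {
    stop("invalid-argument: miRNA must be at least 8 nt, got ", nchar(mirna))
  }
  rc27 <- rna_revcomp(substr(mirna, 2, 7))
  rc38 <- rna_revcomp(substr(mirna, 3, 8))
  rc28 <- rna_revcomp(substr(mirna, 2, 8))
  c("8mer"      = paste0(rc28, "A"),
    "7mer-m8"   = rc28,
    "7mer-1A"   = paste0(rc27, "A"),
    "6mer-n2-7" = rc27,
    "6mer-n3-8" = rc38)
}

# All (possibly overlapping) 1-based start positions of fixed pattern
# `pat` in `text`. Patterns contain only ACGUA so they are regex-safe.
find_all_starts <- function(text, pat) {
  hits <- gregexpr(paste0("(?=", pat, ")"), text, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

#' Classify the seed-match sites of one 3' UTR
#'
#' Locates every occurrence of the five seed-match patterns of `mirna` in
#' the sense strand of `utr` and reports the best (highest-precedence) site
#' type plus all site intervals. Classes are mutually exclusive per locus:
#' a shorter match wholly contained in a recorded longer (higher-precedence)
#' match at the same locus is not double-counted. T and U are
#' interchangeable and matching is case-insensitive.
#'
#' @param utr 3' UTR sequence, sense strand.
#' @param mirna Mature miRNA sequence, 5' to 3'.
#' @param gene_id Optional identifier carried into the annotation.
#' @return A `site_annotation` list: `gene_id`, `best_type`, `sites`
#'   (data frame of `start`, `end`, `type`, 1-based inclusive), and
#'   `site_count` (named integer vector per type).
#' @examples
#' classify_utr("GGCUACCUCAGG", "UGAGGUAGUAGGUUGUAUAGUU")$best_type
#' @export
classify_utr <- function(utr, mirna, gene_id = NA_character_) {
  if (!nzchar(utr) || !nzchar(mirna)) {
    stop("invalid-sequence: empty sequence")
  }
  utr <- as_rna(utr)
  pats <- site_patterns(mirna)
  scan <- scan_seed_sites(utr, pats)
  sites <- data.frame(start = scan$start, end = scan$end, type = scan$type,
                      stringsAsFactors = FALSE)
  if (nrow(sites)) {
    sites <- sites[order(sites$start, sites$end), , drop = FALSE]
    rownames(sites) <- NULL
  }
  structure(list(gene_id = gene_id, best_type = scan$best,
                 sites = sites, site_count = scan$counts),
            class = "site_annotation")
}

# Vector-level site scan shared by classify_utr and the synthetic planter:
# all occurrences of the five patterns in precedence order, dropping any
# occurrence wholly contained in a recorded higher-precedence occurrence.
scan_seed_sites <- function(utr, pats) {
  types <- names(pats)
  st <- integer(0); en <- integer(0); ty <- character(0)
  for (k in seq_along(pats)) {
    starts <- find_all_starts(utr, pats[[k]])
    if (!length(starts)) next
    ends <- starts + nchar(pats[[k]]) - 1L
    if (length(st)) {
      keep <- vapply(seq_along(starts), function(i) {
        !any(st <= starts[i] & en >= ends[i])
      }, TRUE)
      starts <- starts[keep]; ends <- ends[keep]
    }
    if (length(starts)) {
      st <- c(st, starts); en <- c(en, ends)
      ty <- c(ty, rep(types[k], length(starts)))
    }
  }
  counts <- setNames(integer(length(types)), types)
  if (length(ty)) {
    tab <- table(ty)
    counts[names(tab)] <- as.integer(tab)
  }
  best <- types[match(TRUE, counts > 0)]
  if (is.na(best)) best <- "none"
  list(best = best, start = st, end = en, type = ty, counts = counts)
}

#' Classify a set of UTRs against one miRNA
#'
#' @param utrs Named character vector of UTR sequences (names = gene IDs).
#' @inheritParams classify_utr
#' @return Data frame with one row per UTR: `gene_id`, `best_type`, and one
#'   `n_<type>` count column per site type.
#' @export
classify_utrs <- function(utrs, mirna) {
  stopifnot(length(utrs) > 0, !is.null(names(utrs)))
  anns <- lapply(names(utrs), function(g) classify_utr(utrs[[g]], mirna, g))
  counts <- do.call(rbind, lapply(anns, function(a) a$site_count))
  colnames(counts) <- paste0("n_", colnames(counts))
  out <- data.frame(gene_id = names(utrs),
                    best_type = vapply(anns, `[[`, "", "best_type"),
                    counts[, seq_len(5), drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Disrupt a seed-match site by point mutation
#'
#' Replaces nucleotides inside a seed-match interval with their transversion
#' partners (A<->C, G<->U/T), the standard way reporter constructs abolish a
#' site while preserving length and composition class. Two mutations at the
#' center of the seed complement (the default) destroy any seed match at the
#' locus.
#'
#' @param utr UTR sequence containing the site.
#' @param site Integer vector `c(start, end)`, 1-based inclusive, as
#'   reported by [classify_utr()].
#' @param offsets 1-based offsets within the site to mutate (default 3:4).
#' @return The mutated UTR, same length and alphabet (T/U) as the input.
#' @export
mutate_seed_site <- function(utr, site, offsets = c(3L, 4L)) {
  stopifnot(length(site) == 2)
  start <- as.integer(site[1]); end <- as.integer(site[2])
  if (start < 1 || end > nchar(utr) || end < start) {
    stop("invalid-argument: site interval out of sequence bounds")
  }
  if (!length(offsets)) return(utr)
  width <- end - start + 1L
  if (any(offsets < 1 | offsets > width)) {
    stop("invalid-argument: mutation offsets outside the site interval")
  }
  is_rna <- grepl("U", toupper(utr), fixed = TRUE)
  swap <- if (is_rna) c(A = "C", C = "A", G = "U", U = "G")
          else        c(A = "C", C = "A", G = "T", T = "G")
  chars <- strsplit(utr, "")[[1]]
  pos <- start + as.integer(offsets) - 1L
  up <- toupper(chars[pos])
  if (any(!up %in% names(swap))) {
    stop("invalid-sequence: non-nucleotide character at mutation position")
  }
  chars[pos] <- swap[up]
  paste(chars, collapse = "")
}

#' Scan DNA for the degenerate TCF/beta-catenin binding motif
#'
#' Reports every position of a DNA sequence matching the degenerate
#' beta-catenin/TCF binding motif WWCAAWG (forward) or its reverse-strand
#' representation CWTTGWW scanned on the same strand (W = A or T, IUPAC).
#' Overlapping hits are all reported; N never matches W.
#'
#' @param sequence DNA sequence (alphabet ACGTN, case-insensitive).
#' @return Data frame of hits: `position` (1-based start), `orientation`
#'   (`"forward"` or `"reverse"`), `match` (the 7 nt matched text).
#' @examples
#' scan_tcf_motif("GGAACAAAGTT")
#' @export
scan_tcf_motif <- function(sequence) {
  seqU <- toupper(sequence)
  if (grepl("[^ACGTN]", seqU)) {
    stop("invalid-sequence: DNA alphabet (ACGTN) required")
  }
  one <- function(re, label) {
    starts <- find_all_starts(seqU, re)
    if (!length(starts)) {
      return(data.frame(position = integer(0), orientation = character(0),
                        match = character(0), stringsAsFactors = FALSE))
    }
    data.frame(position = starts, orientation = label,
               match = substring(seqU, starts, starts + 6L),
               stringsAsFactors = FALSE)
  }
  hits <- rbind(one("[AT][AT]CAA[AT]G", "forward"),
                one("C[AT]TTG[AT][AT]", "reverse"))
  hits <- hits[order(hits$position, hits$orientation), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file; record IDs (first whitespace-delimited token of
#'   each header) become element names.
#' @param alphabet `"rna"` to coerce T to U, `"dna"` to leave as stored.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  out <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  if (alphabet == "rna") out <- as_rna(out) else out <- toupper(out)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write site annotations as TSV
#'
#' One row per gene with the best site class, per-type counts and the site
#' intervals (1-based inclusive, `start-end:type` separated by commas).
#'
#' @param annotations List of `site_annotation` objects or the data frame
#'   from [classify_utrs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_annotations <- function(annotations, path) {
  if (is.data.frame(annotations)) {
    df <- annotations
  } else {
    df <- do.call(rbind, lapply(annotations, function(a) {
      iv <- if (nrow(a$sites)) {
        paste(sprintf("%d-%d:%s", a$sites$start, a$sites$end, a$sites$type),
              collapse = ",")
      } else ""
      cnt <- as.list(a$site_count[seq_len(5)])
      names(cnt) <- paste0("n_", names(cnt))
      cbind(data.frame(gene_id = a$gene_id, best_type = a$best_type,
                       stringsAsFactors = FALSE),
            as.data.frame(cnt, check.names = FALSE),
            data.frame(sites_1based = iv, stringsAsFactors = FALSE))
    }))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
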