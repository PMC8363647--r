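#' Normalize a nucleotide sequence to the internal DNA alphabet
#'
#' Uppercases and maps U to T; any character outside {A,C,G,T} (after
#' mapping) is an error. Motif definitions are applied in DNA space.
#'
#' @param seq character scalar (may be empty).
#' @return normalized sequence.
#' @export
normalize_seq <- function(seq) {
  s <- chartr("u", "t", toupper(as.character(seq)))
  s <- chartr("U", "T", s)
  if (nchar(s) && grepl("[^ACGT]", s))
    stop("sequence contains characters outside {A,C,G,T,U}")
  s
}

#' Classify the 5'UTR start as TOP, TOP-like or none
#'
#' A TOP (terminal oligopyrimidine) motif is a cytosine at the very 5' end
#' followed by at least `min_run` consecutive pyrimidines (C/T). If the
#' same pattern starts at any of positions 2 to 5 instead, the UTR is
#' TOP-like. TOP takes precedence.
#'
#' @param utr5 5'UTR sequence.
#' @param min_run minimum pyrimidine run length after the leading C
#'   (default 4).
#' @return `"TOP"`, `"TOP_like"` or `"none"`.
#' @export
scan_top <- function(utr5, min_run = 4) {
  s <- normalize_seq(utr5)
  pat <- paste0("C[CT]{", min_run, ",}")
  hit_at <- function(pos) {
    if (nchar(s) < pos + min_run) return(FALSE)
    regexpr(pat, substr(s, pos, nchar(s))) == 1L
  }
  if (hit_at(1)) return("TOP")
  for (p in 2:5) if (hit_at(p)) return("TOP_like")
  "none"
}

#' Find upstream open reading frames
#'
#' A uORF is an ATG whose first base lies in the 5'UTR, together with the
#' first in-frame stop codon (TAA/TAG/TGA) in the concatenated
#' 5'UTR + CDS sequence, provided that stop ends strictly before the last
#' base of the CDS and the total length (ATG through stop, inclusive) is
#' at least `min_len` nt. Overlapping uORFs are all reported. The stop may
#' fall inside the CDS.
#'
#' @param utr5,cds sequences (CDS from its annotated ATG through its stop).
#' @param min_len minimum uORF length in nt (default 9).
#' @return data.frame with columns `start` (1-based offset in the 5'UTR),
#'   `stop_end` (1-based end of the stop codon in the concatenation),
#'   `length` (nt), sorted by `start`; zero rows when no uORF qualifies.
#' @export
find_uorfs <- function(utr5, cds, min_len = 9) {
  u <- normalize_seq(utr5)
  cc <- normalize_seq(cds)
  concat <- paste0(u, cc)
  L5 <- nchar(u)
  L <- nchar(concat)
  empty <- data.frame(start = integer(), stop_end = integer(), length = integer())
  if (L5 == 0 || L < min_len) return(empty)
  hits <- gregexpr("ATG", concat, fixed = TRUE)[[1]]
  starts <- hits[hits > 0 & hits <= L5]
  if (!length(starts)) return(empty)
  stops <- c("TAA", "TAG", "TGA")
  out <- lapply(starts, function(st) {
    j <- st + 3L
    while (j + 2L <= L) {
      cod <- substr(concat, j, j + 2L)
      if (cod %in% stops) {
        stop_end <- j + 2L
        len <- stop_end - st + 1L
        if (stop_end < L && len >= min_len)
          return(data.frame(start = st, stop_end = stop_end, length = len))
        return(NULL)
      }
      j <- j + 3L
    }
    NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out[order(out$start), , drop = FALSE]
}

#' Count AU-rich elements in a 3'UTR
#'
#' Counts non-overlapping, leftmost-first matches of the 9-nt element
#' TATTTAT[AT][AT].
#'
#' @param utr3 3'UTR sequence.
#' @return integer match count.
#' @export
scan_are <- function(utr3) {
  s <- normalize_seq(utr3)
  if (nchar(s) < 9) return(0L)
  hits <- gregexpr("TATTTAT[AT][AT]", s)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

#' TISU status of a gene
#'
#' Primary mode: membership in a curated list of TISU (Translation
#' Initiator of Short 5'UTR) genes. Optional consensus mode scans the
#' context around the annotated start codon (last 4 nt of the 5'UTR plus
#' first 8 nt of the CDS) against the SAASATGGCGGC consensus (S = G/C);
#' the ATG itself must match exactly and at most `max_mismatch`
#' mismatches are allowed elsewhere.
#'
#' @param gene_id gene identifier.
#' @param tisu_list character vector of TISU gene ids (list mode).
#' @param utr5,cds sequences (consensus mode).
#' @param mode `"list"` or `"consensus"`.
#' @param max_mismatch allowed mismatches outside the ATG (default 1).
#' @return logical.
#' @export
tisu_flag <- function(gene_id, tisu_list = NULL, utr5 = NULL, cds = NULL,
                      mode = c("list", "consensus"), max_mismatch = 1) {
  mode <- match.arg(mode)
  if (mode == "list") {
    if (is.null(tisu_list)) stop("tisu_list is required in list mode")
    return(gene_id %in% tisu_list)
  }
  u <- normalize_seq(utr5)
  cc <- normalize_seq(cds)
  if (nchar(u) < 4 || nchar(cc) < 8) return(FALSE)
  ctx <- paste0(substr(u, nchar(u) - 3L, nchar(u)), substr(cc, 1L, 8L))
  consensus <- strsplit("SAASATGGCGGC", "")[[1]]
  obs <- strsplit(ctx, "")[[1]]
  # positions 5-7 are the invariant ATG
  if (!identical(obs[5:7], c("A", "T", "G"))) return(FALSE)
  ok <- vapply(seq_along(consensus), function(i) {
    if (i %in% 5:7) return(TRUE)
    if (consensus[i] == "S") obs[i] %in% c("G", "C") else obs[i] == consensus[i]
  }, logical(1))
  sum(!ok) <= max_mismatch
}

#' 5'UTR folding score
#'
#' `backend = "builtin"` returns minus the maximum number of nested base
#' pairs (Watson-Crick plus, optionally, G-T wobble in DNA space) with a
#' minimum hairpin loop of 3 unpaired bases, computed by dynamic
#' programming. This is a structure proxy: comparable within a run,
#' not on the kcal/mol scale. `backend = "external"` shells out to
#' `RNAfold` (ViennaRNA) when the executable is discoverable and returns
#' the reported minimum free energy in kcal/mol.
#'
#' @param utr5 sequence; sequences shorter than 5 nt score 0.
#' @param backend `"builtin"` or `"external"`.
#' @param wobble allow G-T (G-U) pairs in the builtin proxy (default TRUE).
#' @param per_nt divide the score by sequence length.
#' @return numeric score, `<= 0`.
#' @export
utr5_mfe <- function(utr5, backend = c("builtin", "external"),
                     wobble = TRUE, per_nt = FALSE) {
  backend <- match.arg(backend)
  s <- normalize_seq(utr5)
  n <- nchar(s)
  if (n < 5) return(0)
  if (backend == "builtin") {
    val <- -1.0 * nussinov_pairs(s, 3L, wobble)
  } else {
    exe <- Sys.which("RNAfold")
    if (exe == "") stop("external folding backend requested but RNAfold not found")
    out <- system2(exe, c("--noPS"), input = chartr("T", "U", s), stdout = TRUE)
    last <- out[length(out)]
    val <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", last))
    if (is.na(val)) stop("could not parse RNAfold output")
  }
  if (per_nt) val / n else val
}

#' Annotate transcripts with 5'/3'UTR regulatory features
#'
#' Produces the per-gene feature table used for enrichment analysis:
#' 5'UTR length and folding score, TOP class, uORF count, AU-rich element
#' count and TISU flag.
#'
#' @param records data.frame with columns `gene_id`, `utr5`, `cds`, `utr3`.
#' @param tisu_list character vector of TISU gene ids (may be empty).
#' @param min_top_run TOP pyrimidine run length (default 4).
#' @param min_uorf_len minimum uORF length (default 9).
#' @param mfe_backend `"builtin"` or `"external"`.
#' @return data.frame of class `feature_table` with columns `gene_id`,
#'   `utr5_len`, `utr5_mfe`, `top_class`, `n_uorf`, `n_are`, `tisu`.
#' @export
annotate_transcripts <- function(records, tisu_list = character(),
                                 min_top_run = 4, min_uorf_len = 9,
                                 mfe_backend = "builtin") {
  if (!nrow(records)) stop("no transcript records supplied")
  if (anyDuplicated(records$gene_id))
    stop("duplicate gene_id in transcript records")
  res <- lapply(seq_len(nrow(records)), function(i) {
    u <- normalize_seq(records$utr5[i])
    cc <- normalize_seq(records$cds[i])
    u3 <- normalize_seq(records$utr3[i])
    if (!nchar(cc)) stop("empty CDS for gene ", records$gene_id[i])
    data.frame(
      gene_id = records$gene_id[i],
      utr5_len = nchar(u),
      utr5_mfe = utr5_mfe(u, backend = mfe_backend),
      top_class = scan_top(u, min_top_run),
      n_uorf = nrow(find_uorfs(u, cc, min_uorf_len)),
      n_are = scan_are(u3),
      tisu = records$gene_id[i] %in% tisu_list,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("feature_table", "data.frame")
  out
}
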