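#' Per-class transcript feature specification
#'
#' Controls the planted 5'/3'UTR features of synthetic transcripts for
#' each regulation class. The defaults emulate the qualitative structural
#' profile of translationally upregulated mRNAs: shorter, less structured
#' 5'UTRs with fewer uORFs and more TISU elements than the array
#' background, with TOP and ARE rates left equal across classes.
#'
#' @param up,down,null named lists overriding, per class, any of:
#'   `utr5_meanlog`, `utr5_sdlog`, `utr5_min` (log-normal 5'UTR length in
#'   nt), `p_top`, `p_top_like`, `uorf_lambda` (Poisson mean uORF count),
#'   `are_lambda` (Poisson mean ARE count), `p_tisu`, `p_structured`,
#'   `gc_plain`, `gc_structured` (5'UTR GC content by structure flag).
#' @param min_top_run TOP pyrimidine run used when planting (default 4).
#' @param cds_codon_range range of CDS codon counts (excluding the stop).
#' @param utr3_len_range range of 3'UTR lengths in nt.
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(up = list(), down = list(), null = list(),
                         min_top_run = 4,
                         cds_codon_range = c(50, 150),
                         utr3_len_range = c(100, 300)) {
  base_null <- list(utr5_meanlog = log(150), utr5_sdlog = 0.35, utr5_min = 25,
                    p_top = 0.05, p_top_like = 0.05, uorf_lambda = 0.8,
                    are_lambda = 0.10, p_tisu = 0.01, p_structured = 0.5,
                    gc_plain = 0.40, gc_structured = 0.65)
  base_up <- utils::modifyList(base_null, list(
    utr5_meanlog = log(70), uorf_lambda = 0.15, p_tisu = 0.15,
    p_structured = 0.2))
  base_down <- utils::modifyList(base_null, list(
    uorf_lambda = 1.0, p_structured = 0.7))
  cls <- list(up = utils::modifyList(base_up, up),
              down = utils::modifyList(base_down, down),
              null = utils::modifyList(base_null, null))
  for (cl in cls) {
    probs <- unlist(cl[c("p_top", "p_top_like", "p_tisu", "p_structured")])
    if (any(probs < 0 | probs > 1)) stop("feature probabilities must be in [0,1]")
    if (cl$utr5_min <= 0 || cl$uorf_lambda < 0 || cl$are_lambda < 0)
      stop("length and rate parameters must be positive")
  }
  structure(list(classes = cls, min_top_run = min_top_run,
                 cds_codon_range = cds_codon_range,
                 utr3_len_range = utr3_len_range),
            class = "feature_spec")
}

.BASES <- c("A", "C", "G", "T")

.random_seq <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

.NON_STOP_CODONS <- {
  all3 <- apply(expand.grid(.BASES, .BASES, .BASES), 1, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

.random_cds <- function(n_codons, tisu = FALSE) {
  body <- sample(.NON_STOP_CODONS, n_codons, replace = TRUE)
  if (tisu) {
    # TISU consensus SAASATGGCGGC spans the start codon: CDS must begin ATGGCGGC
    body[1] <- "GCG"
    body[2] <- "GCC"
    cds <- paste0("ATG", paste(body, collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1))
  } else {
    cds <- paste0("ATG", paste(body, collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1))
  }
  cds
}

# replace characters of a string at 1-based positions
.str_assign <- function(s, pos, chars) {
  v <- strsplit(s, "")[[1]]
  v[pos] <- chars
  paste(v, collapse = "")
}

# remove every ATG whose first base falls in the 5'UTR (junction with the
# CDS included) by mutating one base of the match
.strip_utr5_atg <- function(u, cds_head) {
  repeat {
    concat <- paste0(u, cds_head)
    hits <- gregexpr("ATG", concat, fixed = TRUE)[[1]]
    hits <- hits[hits > 0 & hits <= nchar(u)]
    if (!length(hits)) return(u)
    p <- hits[1]
    if (p + 2L <= nchar(u)) {
      u <- .str_assign(u, p + 2L, "C")       # G -> C
    } else {
      u <- .str_assign(u, p, "G")            # junction match: mutate the A
    }
  }
}

# remove every ARE match by mutating one base
.strip_are <- function(s) {
  repeat {
    hit <- regexpr("TATTTAT[AT][AT]", s)
    if (hit == -1L) return(s)
    s <- .str_assign(s, as.integer(hit) + 3L, "G")
  }
}

#' Build one synthetic transcript with planted features
#'
#' Constructs 5'UTR/CDS/3'UTR sequences carrying exactly the requested
#' features, then verifies them with the package's own scanners and
#' retries with fresh random bases until all planted flags are confirmed
#' (sequence backbones occasionally create or destroy motifs by chance).
#'
#' @param gene_id identifier used in error messages.
#' @param utr5_len 5'UTR length in nt.
#' @param top_class `"none"`, `"TOP"` or `"TOP_like"`.
#' @param n_uorf number of planted uORFs (each 9 nt, wholly inside the
#'   5'UTR).
#' @param n_are number of planted AU-rich elements in the 3'UTR.
#' @param tisu plant the TISU consensus across the start codon.
#' @param gc 5'UTR GC content.
#' @param n_codons CDS codon count (excluding the stop codon).
#' @param utr3_len 3'UTR length in nt.
#' @param min_top_run TOP pyrimidine run length.
#' @param max_tries verification retries before giving up (default 100).
#' @return list with `utr5`, `cds`, `utr3`.
#' @export
build_transcript <- function(gene_id, utr5_len, top_class = "none",
                             n_uorf = 0, n_are = 0, tisu = FALSE,
                             gc = 0.45, n_codons = 80, utr3_len = 150,
                             min_top_run = 4, max_tries = 100) {
  front_reserve <- min_top_run + 6L              # TOP region + spacer
  back_reserve <- if (tisu) 4L else 0L           # TISU tail
  need <- front_reserve + back_reserve + 9L * n_uorf
  if (n_uorf > 0 && utr5_len < need)
    stop("gene ", gene_id, ": 5'UTR of ", utr5_len,
         " nt cannot hold ", n_uorf, " planted uORF(s) (needs >= ", need, ")")
  if (tisu && utr5_len < 4)
    stop("gene ", gene_id, ": 5'UTR too short for the TISU consensus tail")
  if (top_class != "none" && utr5_len < min_top_run + 5L)
    stop("gene ", gene_id, ": 5'UTR too short for a planted TOP motif")
  pyr <- c("C", "T")
  pur <- c("A", "G")
  for (try in seq_len(max_tries)) {
    u <- .random_seq(utr5_len, gc)
    # TOP / TOP-like / none at the 5' end
    if (top_class == "TOP") {
      u <- .str_assign(u, 1:(min_top_run + 1L),
                       c("C", sample(pyr, min_top_run, replace = TRUE)))
    } else if (top_class == "TOP_like") {
      off <- sample(2:5, 1)
      u <- .str_assign(u, 1:(off - 1L), sample(pur, off - 1L, replace = TRUE))
      u <- .str_assign(u, off:(off + min_top_run),
                       c("C", sample(pyr, min_top_run, replace = TRUE)))
    }
    cds <- .random_cds(n_codons, tisu = tisu)
    if (tisu) {
      s14 <- sample(c("G", "C"), 2, replace = TRUE)
      u <- .str_assign(u, (utr5_len - 3L):utr5_len, c(s14[1], "A", "A", s14[2]))
    }
    u <- .strip_utr5_atg(u, substr(cds, 1, 2))
    if (n_uorf > 0) {
      lo <- front_reserve + 1L
      hi <- utr5_len - back_reserve - 8L
      starts <- integer(0)
      cand <- sample(lo:hi)
      for (s in cand) {
        if (all(abs(s - starts) >= 9L)) starts <- c(starts, s)
        if (length(starts) == n_uorf) break
      }
      if (length(starts) < n_uorf)
        stop("gene ", gene_id, ": could not place ", n_uorf,
             " non-overlapping uORFs in a ", utr5_len, " nt 5'UTR")
      for (s in starts) {
        block <- paste0("ATG", sample(c("AAA", "CAA", "AGA"), 1),
                        sample(c("TAA", "TAG"), 1))
        u <- .str_assign(u, s:(s + 8L), strsplit(block, "")[[1]])
      }
    }
    u3 <- .strip_are(.random_seq(utr3_len, 0.35))
    if (n_are > 0) {
      if (utr3_len < 9L * n_are)
        stop("gene ", gene_id, ": 3'UTR too short for ", n_are, " planted AREs")
      starts <- integer(0)
      cand <- sample(seq_len(utr3_len - 8L))
      for (s in cand) {
        if (all(abs(s - starts) >= 9L)) starts <- c(starts, s)
        if (length(starts) == n_are) break
      }
      if (length(starts) < n_are)
        stop("gene ", gene_id, ": could not place ", n_are, " AREs")
      for (s in starts)
        u3 <- .str_assign(u3, s:(s + 8L), strsplit("TATTTATAA", "")[[1]])
    }
    # verify every planted feature with the scanners themselves
    ok <- scan_top(u, min_top_run) == top_class &&
      nrow(find_uorfs(u, cds)) == n_uorf &&
      scan_are(u3) == n_are &&
      (!tisu || tisu_flag(gene_id, utr5 = u, cds = cds, mode = "consensus"))
    if (ok) return(list(utr5 = u, cds = cds, utr3 = u3))
  }
  stop("gene ", gene_id, ": could not realise the planted features after ",
       max_tries, " attempts")
}

#' Generate synthetic transcripts with planted regulatory features
#'
#' Draws per-gene feature flags from the class-specific probabilities of
#' the [feature_spec()], builds sequences carrying exactly those features
#' and returns them together with the planted truth. Planted uORF counts
#' are capped at the number of 9-nt blocks the drawn 5'UTR can hold.
#'
#' @param design a [sim_design()] (supplies gene count, truth classes and
#'   the seed; the transcript stream is a fixed offset of the design
#'   seed).
#' @param spec a [feature_spec()].
#' @param truth optional truth table from [plant_truth()].
#' @return list with `records` (data.frame `gene_id`, `utr5`, `cds`,
#'   `utr3`), `truth` (planted feature table: `gene_id`, `status`,
#'   `top_class`, `n_uorf`, `n_are`, `tisu`, `utr5_len`, `structured`)
#'   and `tisu_list` (gene ids flagged TISU).
#' @export
gen_transcripts <- function(design, spec = feature_spec(), truth = NULL) {
  stopifnot(inherits(design, "sim_design"), inherits(spec, "feature_spec"))
  if (is.null(truth)) truth <- plant_truth(design)
  set.seed(as.integer(design$seed) + 10007L)
  rows <- vector("list", nrow(truth))
  feats <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cl <- spec$classes[[truth$status[i]]]
    utr5_len <- max(cl$utr5_min,
                    round(stats::rlnorm(1, cl$utr5_meanlog, cl$utr5_sdlog)))
    r <- stats::runif(4)
    top_class <- if (r[1] < cl$p_top) "TOP"
                 else if (r[1] < cl$p_top + cl$p_top_like) "TOP_like"
                 else "none"
    capacity <- max(0L, (utr5_len - (spec$min_top_run + 6L) - 4L) %/% 9L)
    n_uorf <- min(stats::rpois(1, cl$uorf_lambda), capacity)
    n_are <- stats::rpois(1, cl$are_lambda)
    tisu <- r[2] < cl$p_tisu
    structured <- r[3] < cl$p_structured
    gc <- if (structured) cl$gc_structured else cl$gc_plain
    n_codons <- sample(spec$cds_codon_range[1]:spec$cds_codon_range[2], 1)
    utr3_len <- max(9L * n_are,
                    sample(spec$utr3_len_range[1]:spec$utr3_len_range[2], 1))
    tr <- build_transcript(truth$gene_id[i], utr5_len, top_class, n_uorf,
                           n_are, tisu, gc, n_codons, utr3_len,
                           spec$min_top_run)
    rows[[i]] <- data.frame(gene_id = truth$gene_id[i], utr5 = tr$utr5,
                            cds = tr$cds, utr3 = tr$utr3,
                            stringsAsFactors = FALSE)
    feats[[i]] <- data.frame(gene_id = truth$gene_id[i],
                             status = truth$status[i],
                             top_class = top_class, n_uorf = n_uorf,
                             n_are = n_are, tisu = tisu,
                             utr5_len = utr5_len, structured = structured,
                             stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  ftruth <- do.call(rbind, feats)
  list(records = records, truth = ftruth,
       tisu_list = ftruth$gene_id[ftruth$tisu])
}
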