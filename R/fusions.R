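#' Read one RNA fusion caller's output in the common TSV schema
#'
#' Columns: `gene5, gene3, chrom5, pos5, chrom3, pos3, split_reads,
#' spanning_pairs` and optionally `caller`. Per-caller output adapters are
#' expected to map native formats onto this schema. Malformed rows (missing
#' gene names, non-numeric positions, or a gene fused to itself — read-through
#' artifacts) are skipped and counted.
#'
#' @param path TSV path with a header row.
#' @param caller Caller name to attach when the file has no `caller` column.
#' @return data.frame in the common schema with attribute `n_skipped`.
#' @export
read_fusion_tsv <- function(path, caller = NA_character_) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene5", "gene3", "chrom5", "pos5", "chrom3", "pos3")
  if (!all(required %in% names(d)))
    stop_fmt("%s: missing fusion TSV columns: %s", path,
             paste(setdiff(required, names(d)), collapse = ", "))
  if (!"split_reads" %in% names(d)) d$split_reads <- NA_real_
  if (!"spanning_pairs" %in% names(d)) d$spanning_pairs <- NA_real_
  if (!"caller" %in% names(d)) d$caller <- caller
  d$pos5 <- suppressWarnings(as.numeric(d$pos5))
  d$pos3 <- suppressWarnings(as.numeric(d$pos3))
  bad <- is.na(d$gene5) | is.na(d$gene3) | !nzchar(d$gene5) | !nzchar(d$gene3) |
    is.na(d$pos5) | is.na(d$pos3) | d$gene5 == d$gene3
  if (any(bad)) message(sprintf("%s: skipped %d malformed row(s)", path, sum(bad)))
  out <- d[!bad, c(required, "split_reads", "spanning_pairs", "caller")]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Aggregate RNA fusion calls across callers by gene pair
#'
#' Unions calls over the unordered gene pair: every pair reported by any
#' caller is retained (union-then-targeted-review, not intersection — a real
#' fusion is often reported by a single caller among hundreds of calls).
#' Per-pair, per-caller breakpoints and read support are kept; breakpoints
#' agreeing within `breakpoint_tolerance` at both ends are counted as one
#' distinct junction. An optional priority gene list subsets the union.
#'
#' @param callsets Named list of fusion tables (from [read_fusion_tsv()]) or
#'   file paths; names are used as caller labels where the tables carry none.
#' @param breakpoint_tolerance bp tolerance for counting distinct junctions.
#' @param priority_genes Optional character vector; keep pairs involving any
#'   of these genes.
#' @return data.frame of class `fusion_calls`: `gene5`, `gene3`,
#'   `n_callers`, `callers`, `n_calls`, `n_junctions`, `max_split_reads`,
#'   `max_spanning_pairs`, plus a `breakpoints` list column of per-caller
#'   records.
#' @export
aggregate_fusions <- function(callsets, breakpoint_tolerance = 1000,
                              priority_genes = NULL) {
  if (is.data.frame(callsets)) callsets <- list(callsets)
  nms <- names(callsets) %||% rep(NA_character_, length(callsets))
  tabs <- lapply(seq_along(callsets), function(i) {
    x <- callsets[[i]]
    if (is.character(x)) x <- read_fusion_tsv(x, caller = nms[i])
    if (all(is.na(x$caller)) && !is.na(nms[i])) x$caller <- nms[i]
    x
  })
  all_f <- do.call(rbind, tabs)
  if (is.null(all_f) || nrow(all_f) == 0L) {
    out <- data.frame(gene5 = character(), gene3 = character(),
                      n_callers = integer(), callers = character(),
                      n_calls = integer(), n_junctions = integer(),
                      max_split_reads = numeric(), max_spanning_pairs = numeric())
    out$breakpoints <- list()
    class(out) <- c("fusion_calls", "data.frame")
    return(out)
  }
  pairkey <- vapply(seq_len(nrow(all_f)), function(i)
    paste(sort(c(all_f$gene5[i], all_f$gene3[i])), collapse = "\r"), "")
  rows <- lapply(split(seq_len(nrow(all_f)), pairkey), function(idx) {
    sub <- all_f[idx, , drop = FALSE]
    data.frame(gene5 = sub$gene5[1L], gene3 = sub$gene3[1L],
               n_callers = length(unique(sub$caller)),
               callers = paste(sort(unique(sub$caller)), collapse = ","),
               n_calls = nrow(sub),
               n_junctions = count_junctions(sub$pos5, sub$pos3, breakpoint_tolerance),
               max_split_reads = suppressWarnings(max(c(sub$split_reads, -Inf), na.rm = TRUE)),
               max_spanning_pairs = suppressWarnings(max(c(sub$spanning_pairs, -Inf), na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$max_split_reads[!is.finite(out$max_split_reads)] <- NA_real_
  out$max_spanning_pairs[!is.finite(out$max_spanning_pairs)] <- NA_real_
  out$breakpoints <- lapply(split(seq_len(nrow(all_f)), pairkey),
                            function(idx) all_f[idx, , drop = FALSE])
  rownames(out) <- NULL
  if (!is.null(priority_genes)) {
    keep <- out$gene5 %in% priority_genes | out$gene3 %in% priority_genes
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("fusion_calls", "data.frame")
  out
}

# single-linkage count of distinct junctions among (pos5, pos3) pairs
count_junctions <- function(pos5, pos3, tol) {
  n <- length(pos5)
  if (n <= 1L) return(n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (abs(pos5[a] - pos5[b]) <= tol && abs(pos3[a] - pos3[b]) <= tol) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

#' Annotate SV breakpoints with genes, introns and fusion orientation
#'
#' Labels each breakpoint of each call with the overlapping gene(s)
#' (`"intergenic"` when none). With an exon model, the containing intron is
#' reported in transcription order (a breakpoint between exons 15 and 16 of a
#' 5'->3' transcript is "intron 15"). When the retained side of each
#' breakpoint is known (explicitly, or implied by the call type: a tandem
#' duplication junction retains the right side of its left breakpoint and the
#' left side of its right breakpoint; a deletion the opposite), the gene
#' whose transcription start lies on the retained fragment contributes the 5'
#' end of the predicted fusion.
#'
#' @param calls A `consensus_sv` or [sv_calls()] table (needs `chrom1`,
#'   `pos1`, `chrom2`, `pos2`, `sv_type`).
#' @param genes data.frame with `chrom`, `start`, `end`, `strand`, `gene`
#'   (see [read_gene_bed()]).
#' @param exons Optional data.frame with `gene`, `start`, `end` (one row per
#'   exon; coordinate order, numbering follows strand).
#' @param sides Optional 2-column matrix/data.frame of `"left"`/`"right"`
#'   retained sides per call, overriding the sv_type defaults.
#' @return data.frame with one row per call: `gene1`, `feature1`, `gene2`,
#'   `feature2`, `gene5`, `gene3` (NA when orientation is undetermined).
#' @export
annotate_breakpoints <- function(calls, genes, exons = NULL, sides = NULL) {
  stopifnot(all(c("chrom", "start", "end", "strand", "gene") %in% names(genes)))
  n <- nrow(calls)
  default_sides <- function(type) {
    switch(type,
           DUP = c("right", "left"),
           DEL = c("left", "right"),
           c(NA_character_, NA_character_))
  }
  one_bp <- function(chrom, pos) {
    hit <- genes$chrom == chrom & genes$start <= pos & pos < genes$end
    if (!any(hit)) return(list(gene = "intergenic", feature = NA_character_,
                               strand = NA_character_, row = NA_integer_))
    i <- which(hit)[1L]
    feature <- NA_character_
    if (!is.null(exons)) {
      ex <- exons[exons$gene == genes$gene[i], , drop = FALSE]
      if (nrow(ex) > 0L) {
        ex <- ex[order(ex$start), , drop = FALSE]
        ne <- nrow(ex)
        in_exon <- which(ex$start <= pos & pos < ex$end)
        if (length(in_exon) > 0L) {
          k <- in_exon[1L]
          feature <- sprintf("exon %d", if (genes$strand[i] == "-") ne - k + 1L else k)
        } else {
          k <- findInterval(pos, ex$start)   # pos after exon k (coordinate order)
          if (k >= 1L && k < ne) {
            idx <- if (genes$strand[i] == "-") ne - k else k
            feature <- sprintf("intron %d", idx)
          }
        }
      }
    }
    list(gene = genes$gene[i], feature = feature, strand = genes$strand[i], row = i)
  }
  out <- lapply(seq_len(n), function(i) {
    a <- one_bp(calls$chrom1[i], calls$pos1[i])
    b <- one_bp(calls$chrom2[i], calls$pos2[i])
    sd <- if (!is.null(sides)) as.character(unlist(sides[i, ]))
          else default_sides(calls$sv_type[i])
    five_prime <- function(hit, side) {
      if (is.na(side) || is.na(hit$strand)) return(NA)
      (hit$strand == "+" && side == "left") || (hit$strand == "-" && side == "right")
    }
    f1 <- five_prime(a, sd[1L]); f2 <- five_prime(b, sd[2L])
    g5 <- g3 <- NA_character_
    if (isTRUE(f1) && identical(f2, FALSE)) { g5 <- a$gene; g3 <- b$gene }
    if (isTRUE(f2) && identical(f1, FALSE)) { g5 <- b$gene; g3 <- a$gene }
    data.frame(gene1 = a$gene, feature1 = a$feature,
               gene2 = b$gene, feature2 = b$feature,
               gene5 = g5, gene3 = g3, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a gene model from BED12 (or BED6)
#'
#' Uses rtracklayer to parse BED; BED12 block structure becomes the exon
#' table. Coordinates are returned 0-based half-open.
#'
#' @param path BED file path.
#' @return list with `genes` (`chrom`, `start`, `end`, `strand`, `gene`) and
#'   `exons` (`gene`, `start`, `end`; NULL for BED6).
#' @export
read_gene_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_fmt("read_gene_bed() requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  genes <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      gene = gr$name, stringsAsFactors = FALSE)
  exons <- NULL
  if (!is.null(gr$blocks)) {
    bl <- gr$blocks
    exons <- do.call(rbind, lapply(seq_along(gr), function(i) {
      b <- bl[[i]]
      data.frame(gene = gr$name[i],
                 start = genes$start[i] + GenomicRanges::start(b) - 1L,
                 end = genes$start[i] + GenomicRanges::end(b),
                 stringsAsFactors = FALSE)
    }))
  }
  list(genes = genes, exons = exons)
}
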