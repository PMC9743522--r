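#' Construct a canonical SV call table
#'
#' One row per caller-level structural-variant call: a breakpoint pair in
#' canonical order (chromosomes ordered lexical-numeric; positions ordered
#' within a chromosome), the caller-assigned type, and pass-through metadata.
#' `size` is `pos2 - pos1` for cis calls and `NA` for interchromosomal calls.
#'
#' @param chrom1,pos1,chrom2,pos2 Breakpoint coordinates (vectors).
#' @param sv_type Caller-assigned type (`DEL`, `DUP`, `INV`, `TRA`, `BND`, ...).
#' @param caller Caller name.
#' @param sample Sample name (optional).
#' @param quality Caller-native score, passed through (optional).
#' @param truth_id Ground-truth event id for simulated calls (optional).
#' @return data.frame of class `sv_calls`.
#' @export
sv_calls <- function(chrom1, pos1, chrom2, pos2, sv_type = "BND",
                     caller = NA_character_, sample = NA_character_,
                     quality = NA_real_, truth_id = NA_integer_) {
  n <- length(pos1)
  d <- data.frame(chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
                  chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
                  sv_type = rep_len(as.character(sv_type), n),
                  caller = rep_len(as.character(caller), n),
                  sample = rep_len(as.character(sample), n),
                  quality = rep_len(as.numeric(quality), n),
                  truth_id = rep_len(as.integer(truth_id), n),
                  stringsAsFactors = FALSE)
  r1 <- chrom_rank(d$chrom1); r2 <- chrom_rank(d$chrom2)
  swap <- r1 > r2 | (d$chrom1 == d$chrom2 & d$pos1 > d$pos2)
  if (any(swap)) {
    tmp_c <- d$chrom1[swap]; tmp_p <- d$pos1[swap]
    d$chrom1[swap] <- d$chrom2[swap]; d$pos1[swap] <- d$pos2[swap]
    d$chrom2[swap] <- tmp_c; d$pos2[swap] <- tmp_p
  }
  d$size <- ifelse(d$chrom1 == d$chrom2, d$pos2 - d$pos1, NA_real_)
  class(d) <- c("sv_calls", "data.frame")
  d
}

empty_sv_calls <- function() {
  sv_calls(character(), numeric(), character(), numeric())
}

#' Multi-caller SV consensus under the double-breakpoint rule
#'
#' Two calls are deemed the same event when their chromosome pairs match and
#' both the start and the end breakpoints fall within `tolerance` of each
#' other (inclusive). The caller-assigned type is NOT required to agree,
#' because different callers label the same rearrangement differently (DUP vs
#' BND). Matching is single-linkage: an edge joins every qualifying pair and
#' consensus groups are the connected components. Each group's representative
#' is the medoid member (minimum summed breakpoint distance to the others,
#' ties broken by earliest canonical order).
#'
#' @param callsets Named list of [sv_calls()] tables, one per caller (or a
#'   single table with a `caller` column).
#' @param tolerance Breakpoint tolerance in bp (inclusive; default 1000).
#' @return data.frame of class `consensus_sv`: one row per group with the
#'   representative breakpoints, `sv_type`, `size`, `n_callers`, `n_calls`,
#'   `callers` (comma-separated), `truth_id` (consensus of members, NA if
#'   mixed/unknown) and a `members` list column of member-call row indices
#'   into `attr(, "calls")` (the pooled canonical call table).
#' @export
match_calls <- function(callsets, tolerance = 1000) {
  if (tolerance < 0) stop_fmt("tolerance must be >= 0")
  if (is.data.frame(callsets)) callsets <- list(callsets)
  if (!is.null(names(callsets)))
    callsets <- lapply(names(callsets), function(nm) {
      x <- callsets[[nm]]
      if (all(is.na(x$caller))) x$caller <- nm
      x
    })
  all_calls <- do.call(rbind, lapply(callsets, as.data.frame))
  n <- nrow(all_calls)
  if (n == 0L) {
    res <- data.frame(chrom1 = character(), pos1 = numeric(), chrom2 = character(),
                      pos2 = numeric(), sv_type = character(), size = numeric(),
                      n_callers = integer(), n_calls = integer(), callers = character(),
                      truth_id = integer())
    res$members <- list()
    attr(res, "calls") <- all_calls
    class(res) <- c("consensus_sv", "data.frame")
    return(res)
  }
  all_calls$.id <- seq_len(n)
  # sorted sweep within each chromosome pair: candidate partners lie in a
  # pos1 window of width `tolerance`
  edges_from <- integer(); edges_to <- integer()
  pairkey <- paste(all_calls$chrom1, all_calls$chrom2, sep = "\r")
  for (pk in unique(pairkey)) {
    g <- all_calls[pairkey == pk, , drop = FALSE]
    g <- g[order(g$pos1, g$pos2, g$.id), , drop = FALSE]
    m <- nrow(g)
    if (m < 2L) next
    for (a in seq_len(m - 1L)) {
      b <- a + 1L
      while (b <= m && g$pos1[b] - g$pos1[a] <= tolerance) {
        if (abs(g$pos2[b] - g$pos2[a]) <= tolerance) {
          edges_from <- c(edges_from, g$.id[a]); edges_to <- c(edges_to, g$.id[b])
        }
        b <- b + 1L
      }
    }
  }
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges_from) > 0L)
    gr <- igraph::add_edges(gr, rbind(edges_from, edges_to))
  comp <- igraph::components(gr)$membership
  rows <- lapply(split(seq_len(n), comp), function(members) {
    sub <- all_calls[members, , drop = FALSE]
    k <- length(members)
    if (k == 1L) rep_i <- 1L
    else {
      dist_sum <- rowSums(abs(outer(sub$pos1, sub$pos1, "-"))) +
        rowSums(abs(outer(sub$pos2, sub$pos2, "-")))
      best <- which(dist_sum == min(dist_sum))
      ord <- order(chrom_rank(sub$chrom1[best]), sub$pos1[best],
                   chrom_rank(sub$chrom2[best]), sub$pos2[best],
                   sub$caller[best], sub$.id[best])
      rep_i <- best[ord[1L]]
    }
    tid <- unique(sub$truth_id[!is.na(sub$truth_id)])
    data.frame(chrom1 = sub$chrom1[rep_i], pos1 = sub$pos1[rep_i],
               chrom2 = sub$chrom2[rep_i], pos2 = sub$pos2[rep_i],
               sv_type = sub$sv_type[rep_i],
               size = sub$size[rep_i],
               n_callers = length(unique(sub$caller)),
               n_calls = k,
               callers = paste(sort(unique(sub$caller)), collapse = ","),
               truth_id = if (length(tid) == 1L) tid else NA_integer_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$members <- unname(split(seq_len(n), comp))
  ord <- order(chrom_rank(res$chrom1), res$pos1, chrom_rank(res$chrom2), res$pos2)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "calls") <- all_calls
  attr(res, "tolerance") <- tolerance
  class(res) <- c("consensus_sv", "data.frame")
  res
}

#' Filter consensus SVs by size and caller support
#'
#' Keeps groups supported by at least `min_callers` distinct callers whose
#' size strictly exceeds `min_size` bp. Interchromosomal groups have no size;
#' they pass the size criterion when `keep_trans` is set. Ordering preserved.
#'
#' @param consensus A `consensus_sv` table from [match_calls()].
#' @param min_size Strict lower size bound in bp (default 10 kb: "> 10 kb").
#' @param min_callers Minimum distinct supporting callers (default 2).
#' @param keep_trans Retain interchromosomal groups (default TRUE).
#' @return The filtered `consensus_sv` table.
#' @export
filter_consensus <- function(consensus, min_size = 10000, min_callers = 2L,
                             keep_trans = TRUE) {
  trans <- consensus$chrom1 != consensus$chrom2
  keep <- consensus$n_callers >= min_callers &
    ifelse(trans, keep_trans, !is.na(consensus$size) & consensus$size > min_size)
  out <- consensus[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag consensus SVs present in a matched normal as germline
#'
#' A tumor group is flagged germline when any call from the matched normal
#' sample matches its representative breakpoints under the same
#' double-breakpoint tolerance rule as [match_calls()]; all other groups are
#' flagged somatic. This automates the matched-normal check used to validate
#' somatic status.
#'
#' @param tumor A `consensus_sv` table.
#' @param normal Named list of [sv_calls()] tables from the matched normal.
#' @param tolerance Breakpoint tolerance in bp (inclusive).
#' @return `tumor` with a logical `somatic` column.
#' @export
subtract_normal <- function(tumor, normal, tolerance = 1000) {
  if (is.data.frame(normal)) normal <- list(normal)
  nc <- do.call(rbind, lapply(normal, as.data.frame))
  if (is.null(nc) || nrow(nc) == 0L) {
    tumor$somatic <- rep(TRUE, nrow(tumor))
    return(tumor)
  }
  tumor$somatic <- vapply(seq_len(nrow(tumor)), function(i) {
    hit <- nc$chrom1 == tumor$chrom1[i] & nc$chrom2 == tumor$chrom2[i] &
      abs(nc$pos1 - tumor$pos1[i]) <= tolerance &
      abs(nc$pos2 - tumor$pos2[i]) <= tolerance
    !any(hit)
  }, TRUE)
  tumor
}

#' Read/write SV calls as BEDPE
#'
#' Ten standard BEDPE columns (`chrom1 start1 end1 chrom2 start2 end2 name
#' score strand1 strand2`) followed by `sv_type`, `caller`, `sample` extras.
#' Breakpoints are stored as 1-bp intervals (`start = pos`, `end = pos + 1`).
#'
#' @param calls An [sv_calls()] table (for writing).
#' @param path File path.
#' @return For `read_bedpe`, an [sv_calls()] table; for `write_bedpe`,
#'   `path` invisibly.
#' @export
write_bedpe <- function(calls, path) {
  d <- as.data.frame(calls)
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t.\t.\t%s\t%s\t%s",
                   d$chrom1, format_count(d$pos1), format_count(d$pos1 + 1),
                   d$chrom2, format_count(d$pos2), format_count(d$pos2 + 1),
                   ifelse(is.na(d$truth_id), ".", paste0("truth_", d$truth_id)),
                   ifelse(is.na(d$quality), ".", sprintf("%.6g", d$quality)),
                   d$sv_type, d$caller, d$sample)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_sv_calls())
  d <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                         fill = TRUE)
  if (ncol(d) < 11L) stop_fmt("%s: expected BEDPE with sv_type extras", path)
  name <- as.character(d[[7L]])
  tid <- ifelse(grepl("^truth_", name), sub("^truth_", "", name), NA)
  sv_calls(d[[1L]], d[[2L]], d[[4L]], d[[5L]],
           sv_type = as.character(d[[11L]]),
           caller = if (ncol(d) >= 12L) as.character(d[[12L]]) else NA_character_,
           sample = if (ncol(d) >= 13L) as.character(d[[13L]]) else NA_character_,
           quality = suppressWarnings(as.numeric(as.character(d[[8L]]))),
           truth_id = suppressWarnings(as.integer(tid)))
}
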