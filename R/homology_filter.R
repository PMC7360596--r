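## Uniqueness filters that assign query sequences (genome scaffolds or RAD
## reads) to the non-recombining region, rejecting repeat-driven ambiguous
## placements via second-best-hit rules.

#' Construct a ranked hit group
#'
#' A query together with its alignment hits sorted best-first. In genome mode
#' hits are ranked by ascending E-value; in RAD mode by ascending mismatch
#' count. Ties are broken by descending bitscore, then subject id.
#'
#' @param query_id query identifier.
#' @param hits data.frame with columns among `subject_id`, `evalue`,
#'   `n_base_matches`, `pct_mismatch`, `n_mismatches`, `bitscore`,
#'   `sstart`, `send`.
#' @param mode `"genome"` or `"rad"`; sets the ranking key.
#' @param check if TRUE (default) error on hits not sorted best-first rather
#'   than silently reordering.
#' @return object of class `sg_hitgroup`.
#' @export
sg_hitgroup <- function(query_id, hits, mode = c("genome", "rad"),
                        check = TRUE) {
  mode <- match.arg(mode)
  if (nrow(hits) < 1L) stop("hit group must contain at least one hit")
  key <- if (mode == "genome") hits$evalue else hits$n_mismatches
  if (is.null(key) || anyNA(key))
    stop("missing ranking key (", if (mode == "genome") "evalue" else "n_mismatches",
         ") for query ", query_id)
  if (check && is.unsorted(key)) stop("hits for query ", query_id,
                                      " are not sorted best-first")
  if (!check) {
    bs <- if (is.null(hits$bitscore)) rep(0, nrow(hits)) else hits$bitscore
    hits <- hits[order(key, -bs, hits$subject_id), , drop = FALSE]
  }
  rownames(hits) <- NULL
  structure(list(query_id = as.character(query_id), hits = hits, mode = mode),
            class = "sg_hitgroup")
}

#' @export
print.sg_hitgroup <- function(x, ...) {
  cat(sprintf("Hit group for query %s (%s mode): %d hit(s), best subject %s\n",
              x$query_id, x$mode, nrow(x$hits), x$hits$subject_id[1]))
  invisible(x)
}

#' Uniqueness filter for genome scaffolds
#'
#' A scaffold is accepted into the non-recombining region iff its top hit
#' lands on a region subject with E-value at or below `e_max`, and the second
#' best hit (if any) betrays no ambiguity: the group is rejected when the
#' second hit has E-value at or below `e_max`, or has at least half the
#' top hit's base matches, or at most half the top hit's mismatch
#' percentage. All three second-hit clauses are boundary-inclusive.
#'
#' @param group an [sg_hitgroup()] in genome mode.
#' @param region_subjects character vector of subject ids forming the region.
#' @param e_max top-hit E-value threshold (default 1e-4, inclusive).
#' @return list with `accept` (logical) and `reason` (the first failing
#'   clause, or `"ok"`).
#' @export
filter_genome_scaffold <- function(group, region_subjects, e_max = 1e-4) {
  stopifnot(inherits(group, "sg_hitgroup"))
  h <- group$hits
  top <- h[1, ]
  if (!top$subject_id %in% region_subjects)
    return(list(accept = FALSE, reason = "top_hit_outside_region"))
  if (top$evalue > e_max)
    return(list(accept = FALSE, reason = "top_evalue_above_threshold"))
  if (nrow(h) >= 2L) {
    second <- h[2, ]
    if (second$evalue <= e_max)
      return(list(accept = FALSE, reason = "second_hit_evalue"))
    if (second$n_base_matches >= 0.5 * top$n_base_matches)
      return(list(accept = FALSE, reason = "second_hit_base_matches"))
    if (second$pct_mismatch <= 0.5 * top$pct_mismatch)
      return(list(accept = FALSE, reason = "second_hit_pct_mismatch"))
  }
  list(accept = TRUE, reason = "ok")
}

#' Uniqueness filter for RAD read alignments
#'
#' A read is accepted iff its top hit has at most `max_mismatch` mismatches
#' and the second best hit (if any) has strictly more than double the top
#' hit's mismatches ("double ... or less" rejects, boundary-inclusive).
#'
#' @param group an [sg_hitgroup()] in RAD mode with `n_mismatches` populated.
#' @param max_mismatch top-hit mismatch ceiling (default 4).
#' @return list with `accept` and `reason`.
#' @export
filter_rad_alignment <- function(group, max_mismatch = 4L) {
  stopifnot(inherits(group, "sg_hitgroup"))
  h <- group$hits
  if (is.null(h$n_mismatches) || anyNA(h$n_mismatches))
    stop("n_mismatches missing for query ", group$query_id)
  if (h$n_mismatches[1] > max_mismatch)
    return(list(accept = FALSE, reason = "top_too_many_mismatches"))
  if (nrow(h) >= 2L && h$n_mismatches[2] <= 2 * h$n_mismatches[1])
    return(list(accept = FALSE, reason = "second_hit_mismatches"))
  list(accept = TRUE, reason = "ok")
}

#' Apply the uniqueness filter to every hit group
#'
#' Runs [filter_genome_scaffold()] or [filter_rad_alignment()] (chosen by each
#' group's mode) over a list of hit groups and returns a per-query decision
#' table in deterministic (query-id) order, independent of input order.
#'
#' @param groups list of [sg_hitgroup()] objects.
#' @param region_subjects subject ids of the region (genome mode only).
#' @param ... passed to the per-group filters (`e_max`, `max_mismatch`).
#' @return data.frame with columns `query_id`, `accepted`, `reason`, sorted by
#'   `query_id`; the accepted set is `query_id[accepted]`.
#' @export
collect_region_queries <- function(groups, region_subjects = character(0), ...) {
  if (length(groups) == 0L)
    return(data.frame(query_id = character(0), accepted = logical(0),
                      reason = character(0), stringsAsFactors = FALSE))
  rows <- lapply(groups, function(g) {
    res <- if (g$mode == "genome")
      filter_genome_scaffold(g, region_subjects, ...)
    else filter_rad_alignment(g, ...)
    data.frame(query_id = g$query_id, accepted = res$accept,
               reason = res$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$query_id), ]
  rownames(out) <- NULL
  out
}

#' Build hit-group fixtures
#'
#' Turns a plain list specification into [sg_hitgroup()] objects, e.g. for
#' testing the filters; round-trips bit-exactly through the BLAST-tabular
#' writer/reader.
#'
#' @param spec list; each element a list with `query_id`, and `hits` a
#'   data.frame of ranked hits (best first).
#' @param mode `"genome"` or `"rad"`.
#' @return list of [sg_hitgroup()] objects (empty spec gives an empty list).
#' @export
make_hit_fixture <- function(spec, mode = "genome") {
  lapply(spec, function(s) sg_hitgroup(s$query_id, s$hits, mode = mode))
}

## ---- BLAST tabular I/O (12-column outfmt-6 dialect) ------------------------

BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Write / read hit groups as 12-column BLAST tabular
#'
#' Standard outfmt-6 columns (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore), tab-separated, no header.
#' `pident` is reconstructed as `100 - pct_mismatch` and `length` as the
#' alignment length implied by `n_base_matches` and `pident` when those
#' fields are present.
#'
#' @param groups list of [sg_hitgroup()] objects.
#' @param path file path.
#' @param mode ranking mode for groups read back in.
#' @return `read_blast_tab` returns a list of hit groups (one per distinct
#'   qseqid, input order of first appearance).
#' @export
write_blast_tab <- function(groups, path) {
  rows <- do.call(rbind, lapply(groups, function(g) {
    h <- g$hits
    n <- nrow(h)
    pident <- if (!is.null(h$pct_mismatch)) 100 - h$pct_mismatch else rep(100, n)
    alen <- if (!is.null(h$align_length)) h$align_length
            else if (!is.null(h$n_base_matches)) {
              al <- round(h$n_base_matches / pmax(pident, 1e-9) * 100)
              pmax(al, h$n_base_matches)
            } else rep(0L, n)
    mism <- if (!is.null(h$n_mismatches)) h$n_mismatches
            else round(alen * (100 - pident) / 100)
    data.frame(qseqid = g$query_id,
               sseqid = h$subject_id,
               pident = sprintf("%.3f", pident),
               length = as.integer(alen),
               mismatch = as.integer(mism),
               gapopen = 0L,
               qstart = 1L,
               qend = as.integer(alen),
               sstart = if (!is.null(h$sstart)) as.integer(h$sstart) else 1L,
               send = if (!is.null(h$send)) as.integer(h$send) else as.integer(alen),
               evalue = sprintf("%.3g", if (!is.null(h$evalue)) h$evalue else 0),
               bitscore = sprintf("%.1f", if (!is.null(h$bitscore)) h$bitscore else 0),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_blast_tab
#' @export
read_blast_tab <- function(path, mode = c("genome", "rad")) {
  mode <- match.arg(mode)
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    col.names = BLAST6_COLS)
  qids <- unique(tab$qseqid)
  lapply(qids, function(q) {
    sub <- tab[tab$qseqid == q, ]
    hits <- data.frame(subject_id = sub$sseqid,
                       evalue = sub$evalue,
                       pct_mismatch = 100 - sub$pident,
                       align_length = sub$length,
                       n_base_matches = round(sub$length * sub$pident / 100),
                       n_mismatches = sub$mismatch,
                       bitscore = sub$bitscore,
                       sstart = sub$sstart, send = sub$send,
                       stringsAsFactors = FALSE)
    sg_hitgroup(q, hits, mode = mode, check = FALSE)
  })
}

#' Read RAD alignments from a SAM-subset text file
#'
#' Minimal parser for the columns the RAD filter needs: QNAME, FLAG, RNAME,
#' POS and the `NM:i:` mismatch tag. Unmapped records (FLAG bit 0x4) are
#' skipped. Each query's records become one RAD-mode hit group ranked by
#' ascending mismatches.
#'
#' @param path SAM file path (plain text; header lines ignored).
#' @return list of [sg_hitgroup()] objects in RAD mode.
#' @export
read_sam_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  recs <- lapply(parts, function(p) {
    flag <- as.integer(p[2])
    if (bitwAnd(flag, 4L) != 0L) return(NULL)
    nm <- grep("^NM:i:", p, value = TRUE)
    data.frame(query_id = p[1],
               subject_id = p[3],
               pos = as.integer(p[4]),
               n_mismatches = if (length(nm)) as.integer(sub("^NM:i:", "", nm[1])) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) return(list())
  lapply(unique(recs$query_id), function(q) {
    sub <- recs[recs$query_id == q, c("subject_id", "pos", "n_mismatches")]
    sg_hitgroup(q, sub, mode = "rad", check = FALSE)
  })
}

#' Write filter decisions as TSV
#'
#' @param decisions data.frame from [collect_region_queries()].
#' @param path file path.
#' @export
write_filter_decisions <- function(decisions, path) {
  write.table(decisions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
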