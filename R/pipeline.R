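#' Run the CIS discovery pipeline on a set of orthologous gene models
#'
#' For every anchor gene, pairs its introns with each target species'
#' introns ([correspond_introns()]), aligns each corresponding intron pair
#' ([local_align()]), applies the significance filter (Plus/Plus is
#' guaranteed by construction, E-value `<= max_evalue` inclusive), keeps
#' the order-consistent chain ([chain_order_consistent()]), takes the
#' anchor-side union of the surviving alignments, and intersects the
#' per-target covers ([intersect_multispecies()]) into CIS calls conserved
#' in the full target set. Per-target conserved-nucleotide counts (union,
#' anchor side) are accumulated into a conservation report.
#'
#' @param genes Named list: species -> named list of [gene_model()] objects
#'   (gene ids shared across species).
#' @param anchor Anchor species (must be a name of `genes`).
#' @param targets Character vector of target species.
#' @param scheme,params Alignment scheme and Karlin-Altschul parameters.
#' @param max_evalue Inclusive significance bound (default `9e-10`).
#' @param min_cis_len Minimum CIS call length (default 30 nt).
#' @param word,band,xdrop Seeding and extension controls, see
#'   [local_align()].
#' @return List of class `cis_result`: `calls` (gene-local CIS intervals
#'   with species set and mean identity), `per_target_nt`, `report`
#'   (per-target conservation accounting), `hsps` (chained HSPs with
#'   metadata), `anchor`, `targets`.
#' @export
find_cis <- function(genes, anchor, targets, scheme = scoring_scheme(),
                     params = default_ka_params(scheme),
                     max_evalue = 9e-10, min_cis_len = 30L,
                     word = 11L, band = 40L, xdrop = 30L) {
  stopifnot(anchor %in% names(genes), all(targets %in% names(genes)))
  anchor_genes <- genes[[anchor]]
  counts <- setNames(numeric(length(targets)), targets)
  calls <- data.frame()
  per_target_nt <- data.frame()
  all_hsps <- data.frame()
  for (gid in names(anchor_genes)) {
    ga <- anchor_genes[[gid]]
    ia <- extract_introns(ga)
    if (nrow(ia) == 0L) next
    # per intron ordinal -> per target -> merged anchor-side intervals
    covers <- lapply(seq_len(max(ia$ordinal)), function(i)
      setNames(vector("list", length(targets)), targets))
    identities <- list()
    for (tg in targets) {
      gt <- genes[[tg]][[gid]]
      if (is.null(gt)) next
      it <- extract_introns(gt)
      pairing <- correspond_introns(ga, gt)
      for (r in seq_len(nrow(pairing))) {
        oa <- pairing$ordinal_a[r]; ob <- pairing$ordinal_b[r]
        qa <- ia$sequence[match(oa, ia$ordinal)]
        qb <- it$sequence[match(ob, it$ordinal)]
        if (is.na(qa) || is.na(qb)) next
        hs <- local_align(qa, qb, scheme, params, max_evalue = Inf,
                          word = word, band = band, xdrop = xdrop)
        hs <- filter_hsps(hs, max_evalue)
        hs <- chain_order_consistent(hs)
        if (nrow(hs) == 0L) {
          covers[[oa]][[tg]] <- intervals_df()
          next
        }
        hs$gene_id <- gid; hs$intron_ordinal <- oa; hs$target <- tg
        all_hsps <- rbind(all_hsps, hs)
        covers[[oa]][[tg]] <- conserved_intervals(hs, "query")
      }
    }
    for (oa in ia$ordinal) {
      pt <- covers[[oa]]
      pt[vapply(pt, is.null, logical(1))] <-
        list(intervals_df())  # unpaired targets cover nothing
      for (tg in targets) {
        nt <- interval_total(pt[[tg]])
        counts[tg] <- counts[tg] + nt
        if (nt > 0)
          per_target_nt <- rbind(per_target_nt, data.frame(
            gene_id = gid, intron_ordinal = oa, target = tg,
            conserved_nt = nt, stringsAsFactors = FALSE))
      }
      runs <- intersect_multispecies(pt, min_len = min_cis_len)
      if (nrow(runs) > 0L) {
        off <- ia$start[match(oa, ia$ordinal)]
        sup <- if (nrow(all_hsps) == 0L) all_hsps else
          all_hsps[all_hsps$gene_id == gid & all_hsps$intron_ordinal == oa, ,
                   drop = FALSE]
        mean_id <- vapply(seq_len(nrow(runs)), function(i) {
          ov <- sup[sup$q_start < runs$end[i] & sup$q_end > runs$start[i], ,
                    drop = FALSE]
          if (nrow(ov) == 0L) NA_real_ else mean(ov$identity)
        }, numeric(1))
        calls <- rbind(calls, data.frame(
          anchor_species = anchor, gene_id = gid, intron_ordinal = oa,
          start = off + runs$start, end = off + runs$end,
          intron_start = runs$start, intron_end = runs$end,
          conserved_in = runs$conserved_in, mean_identity = mean_id,
          stringsAsFactors = FALSE))
      }
    }
  }
  report <- build_report(anchor, counts,
                         total_intronic_nucleotides(anchor_genes))
  structure(list(calls = calls, per_target_nt = per_target_nt,
                 report = report, hsps = all_hsps, anchor = anchor,
                 targets = targets),
            class = "cis_result")
}

#' @export
print.cis_result <- function(x, ...) {
  cat(sprintf("<cis_result> anchor %s vs {%s}: %d CIS call(s)\n",
              x$anchor, paste(x$targets, collapse = ", "), nrow(x$calls)))
  print(x$report)
  invisible(x)
}

#' Compare CIS calls with planted truth
#'
#' A planted CIS counts as recovered when some call in the same gene and
#' intron overlaps at least `min_overlap` of its length (anchor-species
#' coordinates). Calls in introns where nothing was planted are false
#' calls.
#'
#' @param calls `calls` component of a [find_cis()] result.
#' @param truth `truth$cis` table of [simulate_family()].
#' @param anchor Anchor species of the calls.
#' @param min_overlap Minimum recovered fraction of the truth interval
#'   (default 0.5).
#' @return List: `recall`, `n_truth`, `n_recovered`, `n_false_calls`.
#' @export
cis_recall <- function(calls, truth, anchor, min_overlap = 0.5) {
  tr <- truth[truth$species == anchor, , drop = FALSE]
  recovered <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    cc <- calls[calls$gene_id == tr$gene_id[i] &
                  calls$intron_ordinal == tr$intron_ordinal[i], ,
                drop = FALSE]
    if (nrow(cc) == 0L) next
    ov <- pmin(cc$end, tr$end[i]) - pmax(cc$start, tr$start[i])
    recovered[i] <- sum(pmax(ov, 0)) >= min_overlap * (tr$end[i] - tr$start[i])
  }
  planted_key <- paste(tr$gene_id, tr$intron_ordinal)
  false_calls <- calls[!paste(calls$gene_id, calls$intron_ordinal) %in%
                         planted_key, , drop = FALSE]
  list(recall = if (nrow(tr)) mean(recovered) else NA_real_,
       n_truth = nrow(tr), n_recovered = sum(recovered),
       n_false_calls = nrow(false_calls))
}

#' Write pipeline outputs as tab-separated tables
#'
#' Emits the CIS call table, the conservation report (the machine-readable
#' form of the per-target conservation tables), and the chained HSP table
#' (1-based closed coordinates in this report only).
#'
#' @param result A [find_cis()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_cis_tables <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(calls = file.path(dir, "cis_calls.tsv"),
             report = file.path(dir, "conservation_report.tsv"),
             hsps = file.path(dir, "hsps.tsv"),
             bed = file.path(dir, "cis_calls.bed"))
  write.table(result$calls, paths["calls"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(result$report, paths["report"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  h <- result$hsps
  if (nrow(h) > 0) {
    h$q_start <- h$q_start + 1L  # 1-based closed in the exported report
    h$s_start <- h$s_start + 1L
  }
  write.table(h, paths["hsps"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_cis_bed(result$calls, paths["bed"])
  invisible(paths)
}
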