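#' Simulation configuration for synthetic orthologous gene families
#'
#' The defaults emulate the study design at desk scale: four species on the
#' fixed tree `(zebrafish,(chicken,(mouse,human)))` with relative divergence
#' times 400 (bony-vertebrate split), 310 (bird/mammal), and 100
#' (rodent/primate) million years; exons diverged to ~70% terminal identity
#' between the deepest pair, background introns diverged near saturation
#' (~30% identity, close to the 25% random floor), and a small number of
#' planted low-divergence intronic segments (the CISs, ~80% identity across
#' the deepest pair). Substitutions follow the Jukes-Cantor model; indels
#' occur in background intron sequence only.
#'
#' @param n_genes Number of orthologous genes (default 5).
#' @param introns_per_gene Introns in the reference transcript (default 6).
#' @param intron_length_range,exon_length_range,cis_length_range Length
#'   ranges (nt) sampled uniformly.
#' @param n_planted_cis Number of planted CISs across the family (default 8),
#'   at most one per intron.
#' @param exon_identity,cis_identity,background_identity Target terminal
#'   identities between the deepest species pair; per-branch rates are
#'   derived from them.
#' @param indel_rate Background-intron indel rate per site per unit time.
#' @param indel_length_geometric_p Geometric length parameter for indels.
#' @param duplication Plant a tandem-duplicated conserved segment pair in
#'   one intron (default FALSE).
#' @param exonize Add, in every species, a transcript variant that exonizes
#'   the first planted CIS, with AG/GT splice flanks planted around it
#'   (default FALSE).
#' @param stop_skip Plant a single-codon stop difference (human TAA vs
#'   mouse TGG) in the first planted CIS, removing chance stop differences
#'   elsewhere (default FALSE).
#' @param frameshift Insert a single nucleotide in the middle of the human
#'   copy of the last planted CIS (default FALSE).
#' @param seed RNG seed for the single global stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5L, introns_per_gene = 6L,
                       intron_length_range = c(2500L, 3500L),
                       exon_length_range = c(120L, 200L),
                       cis_length_range = c(150L, 400L),
                       n_planted_cis = 8L,
                       exon_identity = 0.70, cis_identity = 0.80,
                       background_identity = 0.30,
                       indel_rate = 1e-4, indel_length_geometric_p = 0.3,
                       duplication = FALSE, exonize = FALSE,
                       stop_skip = FALSE, frameshift = FALSE, seed = 1L) {
  stopifnot(n_genes >= 1, introns_per_gene >= 1, n_planted_cis >= 0,
            exon_identity > 0, exon_identity <= 1,
            cis_identity > 0, cis_identity <= 1,
            background_identity > 0, background_identity <= 1,
            indel_rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# fixed 4-taxon topology with branch lengths in relative MY
SIM_TREE <- list(
  species = c("zebrafish", "chicken", "mouse", "human"),
  # (zebrafish:400,((chicken:310,(mouse:100,human:100)n2:210)n1:90)root
  branches = list(root_zebrafish = 400, root_n1 = 90, n1_chicken = 310,
                  n1_n2 = 210, n2_mouse = 100, n2_human = 100),
  deepest_path = 800  # zebrafish <-> any other terminal
)

# Jukes-Cantor rate giving `identity` between the deepest terminal pair
jc_rate_for_identity <- function(identity, path = SIM_TREE$deepest_path) {
  p <- 1 - identity
  if (p >= 0.75) stop("identity below the Jukes-Cantor saturation floor")
  -3 / (4 * path) * log(1 - 4 * p / 3)
}

#' Evolve a DNA sequence along one branch
#'
#' Jukes-Cantor substitutions: each site is substituted with probability
#' `3/4 * (1 - exp(-4 * t * rate / 3))`, drawing uniformly among the other
#' three bases. Indel events are Poisson with mean
#' `indel_rate * t * length`; each is an insertion or deletion (equal
#' probability) of geometric length. Uses the global RNG stream unless
#' `seed` is given, in which case the result is a deterministic function of
#' the inputs.
#'
#' @param seq DNA string.
#' @param t Branch length (time units).
#' @param rate Substitution rate per site per time unit.
#' @param indel_rate Indel event rate per site per time unit.
#' @param indel_p Geometric length parameter (mean length `1/p`).
#' @param seed Optional RNG seed.
#' @return Evolved DNA string.
#' @export
evolve_sequence <- function(seq, t, rate, indel_rate = 0, indel_p = 0.3,
                            seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
      evolve_sequence(seq, t, rate, indel_rate, indel_p)))
  }
  stopifnot(t >= 0, rate >= 0)
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  if (n == 0L) return(seq)
  p_sub <- 0.75 * (1 - exp(-4 * t * rate / 3))
  if (p_sub > 0) {
    hit <- which(runif(n) < p_sub & x %in% c("A", "C", "G", "T"))
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      for (i in hit) {
        x[i] <- sample(setdiff(bases, x[i]), 1L)
      }
    }
  }
  if (indel_rate > 0) {
    n_ev <- rpois(1L, indel_rate * t * n)
    if (n_ev > 0) {
      pos <- sort(sample.int(length(x), min(n_ev, length(x))),
                  decreasing = TRUE)
      for (p in pos) {
        len <- min(rgeom(1L, indel_p) + 1L, 20L)
        if (runif(1) < 0.5) {  # deletion
          x <- x[-(p:min(p + len - 1L, length(x)))]
        } else {               # insertion
          ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          x <- append(x, ins, after = p)
        }
      }
    }
  }
  paste(x, collapse = "")
}

# evolve one ancestral segment down the fixed tree; returns named list of
# terminal sequences; traversal order is fixed for determinism
evolve_down_tree <- function(seq, rate, indel_rate = 0, indel_p = 0.3) {
  b <- SIM_TREE$branches
  zf <- evolve_sequence(seq, b$root_zebrafish, rate, indel_rate, indel_p)
  n1 <- evolve_sequence(seq, b$root_n1, rate, indel_rate, indel_p)
  ck <- evolve_sequence(n1, b$n1_chicken, rate, indel_rate, indel_p)
  n2 <- evolve_sequence(n1, b$n1_n2, rate, indel_rate, indel_p)
  mo <- evolve_sequence(n2, b$n2_mouse, rate, indel_rate, indel_p)
  hu <- evolve_sequence(n2, b$n2_human, rate, indel_rate, indel_p)
  list(zebrafish = zf, chicken = ck, mouse = mo, human = hu)
}

#' Simulate an orthologous gene family with planted truth
#'
#' Assembles an ancestral gene per locus from exon and intron segments,
#' plants conserved intronic segments (and optional duplication,
#' exonization, stop-skip and frameshift features), evolves every segment
#' down the fixed 4-taxon tree with per-feature rates, and reassembles
#' per-species gene models. All randomness comes from one global stream
#' seeded with `config$seed`. Canonical `GT`/`AG` dinucleotides are written
#' at every intron boundary.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, per-species FASTA + GFF3,
#'   a truth BED, and a JSON manifest are written there.
#' @return List with `genes` (named list: species -> list of
#'   [gene_model()]) and `truth` (planted CIS intervals per species,
#'   duplication intervals, stop-skip and frameshift descriptors, exonized
#'   transcript ids).
#' @export
simulate_family <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rates <- list(exon = jc_rate_for_identity(config$exon_identity),
                cis = jc_rate_for_identity(config$cis_identity),
                bg = jc_rate_for_identity(config$background_identity))
  species <- SIM_TREE$species
  n_int <- config$introns_per_gene
  slots <- expand.grid(gene = seq_len(config$n_genes),
                       intron = seq_len(n_int))
  if (config$n_planted_cis > nrow(slots))
    stop("more planted CISs than intron slots")
  planted <- slots[sample.int(nrow(slots), config$n_planted_cis), ,
                   drop = FALSE]
  dup_slot <- NULL
  if (config$duplication) {
    free <- slots[!paste(slots$gene, slots$intron) %in%
                    paste(planted$gene, planted$intron), , drop = FALSE]
    if (nrow(free) == 0L) stop("no free intron for the duplication")
    dup_slot <- free[1L, ]
  }

  genes <- setNames(vector("list", length(species)), species)
  for (sp in species) genes[[sp]] <- list()
  truth_cis <- data.frame(cis_id = character(), species = character(),
                          gene_id = character(), intron_ordinal = integer(),
                          start = integer(), end = integer(),
                          stringsAsFactors = FALSE)
  truth_dup <- data.frame(species = character(), gene_id = character(),
                          intron_ordinal = integer(), a_start = integer(),
                          a_end = integer(), b_start = integer(),
                          b_end = integer(), stringsAsFactors = FALSE)
  truth_stop <- NULL
  truth_fs <- NULL
  truth_exo <- data.frame(gene_id = character(), transcript_id = character(),
                          cis_id = character(), stringsAsFactors = FALSE)

  cis_counter <- 0L
  margin <- 60L
  # feature-to-CIS assignment: ids are given in generation order (gene, then
  # intron); exonization and the stop-skip share the first CIS, the
  # frameshift goes to the last one so the two codon-level plants never
  # collide when two or more CISs exist
  n_cis <- config$n_planted_cis
  all_cis_ids <- if (n_cis > 0) sprintf("cis%02d", seq_len(n_cis))
    else character(0)
  exo_cid <- if (config$exonize && n_cis >= 1L) all_cis_ids[1L]
    else NA_character_
  ss_cid <- if (config$stop_skip && n_cis >= 1L) all_cis_ids[1L]
    else NA_character_
  fs_cid <- if (config$frameshift && n_cis >= 1L) all_cis_ids[n_cis]
    else NA_character_

  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("gene%02d", g)
    # segment table for the ancestral gene, in order
    segs <- list()  # each: type, role ("exon"/"bg"/"cis"/"dup"), exon/intron
    add_seg <- function(type, seq, intron = NA_integer_,
                        exon = NA_integer_, tag = NA_character_) {
      segs[[length(segs) + 1L]] <<- list(type = type, seq = seq,
                                         intron = intron, exon = exon,
                                         tag = tag)
    }
    for (k in seq_len(n_int + 1L)) {
      elen <- sample(config$exon_length_range[1]:config$exon_length_range[2],
                     1L)
      add_seg("exon", random_dna(elen), exon = k)
      if (k <= n_int) {
        ilen <- sample(
          config$intron_length_range[1]:config$intron_length_range[2], 1L)
        has_cis <- any(planted$gene == g & planted$intron == k)
        has_dup <- !is.null(dup_slot) && dup_slot$gene == g &&
          dup_slot$intron == k
        if (has_cis) {
          cis_counter <- cis_counter + 1L
          cid <- sprintf("cis%02d", cis_counter)
          clen <- sample(config$cis_length_range[1]:config$cis_length_range[2],
                         1L)
          clen <- clen - clen %% 3L  # whole codons, for frame analyses
          pos <- sample(margin:(ilen - clen - margin), 1L)
          add_seg("bg", random_dna(pos), intron = k)
          add_seg("cis", random_dna(clen), intron = k, tag = cid)
          add_seg("bg", random_dna(ilen - pos - clen), intron = k)
        } else if (has_dup) {
          dlen <- 120L; spacer <- 150L
          dup_seq <- random_dna(dlen)
          pos <- sample(margin:(ilen - 2L * dlen - spacer - margin), 1L)
          add_seg("bg", random_dna(pos), intron = k)
          add_seg("dup", dup_seq, intron = k, tag = "dupA")
          add_seg("bg", random_dna(spacer), intron = k)
          add_seg("dup", dup_seq, intron = k, tag = "dupB")
          add_seg("bg", random_dna(ilen - pos - 2L * dlen - spacer),
                  intron = k)
        } else {
          add_seg("bg", random_dna(ilen), intron = k)
        }
      }
    }

    # evolve each segment down the tree
    evolved <- lapply(segs, function(sg) {
      rate <- switch(sg$type, exon = rates$exon, cis = rates$cis,
                     dup = rates$cis, bg = rates$bg)
      ir <- if (sg$type == "bg") config$indel_rate else 0
      evolve_down_tree(sg$seq, rate, ir, config$indel_length_geometric_p)
    })

    # optional feature edits at segment level -------------------------------
    seg_tag <- vapply(segs, function(sg)
      if (is.na(sg$tag)) "" else sg$tag, character(1))
    seg_type <- vapply(segs, function(sg) sg$type, character(1))

    for (si in seq_along(segs)) {
      tag <- seg_tag[si]
      if (tag == "" || seg_type[si] != "cis") next
      if (!is.na(ss_cid) && tag == ss_cid && is.null(truth_stop)) {
        # remove chance stop differences between mouse and human, then
        # plant TAA (human) vs TGG (mouse) at a central codon (+1 frame)
        mo <- evolved[[si]]$mouse; hu <- evolved[[si]]$human
        nc <- nchar(hu) %/% 3L
        set_codon <- function(s, k, cod) {
          paste0(substring(s, 1, 3 * (k - 1)), cod,
                 substring(s, 3 * k + 1, nchar(s)))
        }
        get_codon <- function(s, k) substring(s, 3 * k - 2, 3 * k)
        for (k in seq_len(nc)) {
          cm <- get_codon(mo, k); ch <- get_codon(hu, k)
          if (xor(cm %in% STOP_CODONS, ch %in% STOP_CODONS))
            mo <- set_codon(mo, k, ch)
        }
        kk <- max(1L, nc %/% 2L)
        hu <- set_codon(hu, kk, "TAA")
        mo <- set_codon(mo, kk, "TGG")
        evolved[[si]]$mouse <- mo; evolved[[si]]$human <- hu
        truth_stop <- list(cis_id = tag, gene_id = gid,
                           codon_index = kk, species_with_stop = "human",
                           stop_codon = "TAA", other_codon = "TGG",
                           other_aa = "W")
      }
      if (!is.na(fs_cid) && tag == fs_cid && is.null(truth_fs)) {
        hu <- evolved[[si]]$human
        at <- nchar(hu) %/% 2L
        ins <- sample(c("A", "C", "G", "T"), 1L)
        evolved[[si]]$human <- paste0(substring(hu, 1, at), ins,
                                      substring(hu, at + 1, nchar(hu)))
        truth_fs <- list(cis_id = tag, gene_id = gid, species = "human",
                         offset_in_cis = at, indel_length = 1L,
                         frame_delta = 1L)
      }
      if (!is.na(exo_cid) && tag == exo_cid) {
        # plant AG upstream / GT downstream splice flanks in every species
        for (sp in species) {
          left <- evolved[[si - 1L]][[sp]]
          right <- evolved[[si + 1L]][[sp]]
          substr(left, nchar(left) - 1L, nchar(left)) <- "AG"
          substr(right, 1L, 2L) <- "GT"
          evolved[[si - 1L]][[sp]] <- left
          evolved[[si + 1L]][[sp]] <- right
        }
      }
    }

    # reassemble per species ------------------------------------------------
    for (sp in species) {
      pieces <- vapply(evolved, function(e) e[[sp]], character(1))
      # canonical splice dinucleotides at intron boundaries
      lens <- nchar(pieces)
      ends <- cumsum(lens)
      starts <- ends - lens  # 0-based segment starts
      seq <- paste(pieces, collapse = "")
      exon_iv <- intervals_df()
      cis_iv <- list()
      dup_iv <- list()
      intron_bounds <- list()
      cur_intron <- NA_integer_
      for (si in seq_along(segs)) {
        if (seg_type[si] == "exon") {
          exon_iv <- rbind(exon_iv, intervals_df(starts[si], ends[si]))
        } else {
          k <- segs[[si]]$intron
          if (is.null(intron_bounds[[as.character(k)]]))
            intron_bounds[[as.character(k)]] <- c(starts[si], ends[si])
          else intron_bounds[[as.character(k)]][2] <- ends[si]
          if (seg_type[si] == "cis")
            cis_iv[[seg_tag[si]]] <- c(starts[si], ends[si])
          if (seg_type[si] == "dup")
            dup_iv[[seg_tag[si]]] <- c(starts[si], ends[si])
        }
      }
      for (k in names(intron_bounds)) {
        b <- intron_bounds[[k]]
        substr(seq, b[1] + 1L, b[1] + 2L) <- "GT"
        substr(seq, b[2] - 1L, b[2]) <- "AG"
      }
      transcripts <- list(transcript_variant(paste0(gid, "_t1"), exon_iv,
                                             cds_start = 0L))
      if (!is.na(exo_cid) && exo_cid %in% names(cis_iv)) {
        civ <- cis_iv[[exo_cid]]
        ex2 <- rbind(exon_iv, intervals_df(civ[1], civ[2]))
        ex2 <- ex2[order(ex2$start), ]
        tid <- paste0(gid, "_tx")
        transcripts[[2L]] <- transcript_variant(tid, ex2, cds_start = 0L)
        if (sp == species[1L] &&
            !tid %in% truth_exo$transcript_id)
          truth_exo <- rbind(truth_exo, data.frame(
            gene_id = gid, transcript_id = tid, cis_id = exo_cid,
            stringsAsFactors = FALSE))
      }
      genes[[sp]][[gid]] <- gene_model(gid, sp, seq, transcripts,
                                       reference_transcript_id =
                                         paste0(gid, "_t1"))
      for (cid in names(cis_iv)) {
        k <- segs[[which(seg_tag == cid)]]$intron
        truth_cis <- rbind(truth_cis, data.frame(
          cis_id = cid, species = sp, gene_id = gid, intron_ordinal = k,
          start = cis_iv[[cid]][1], end = cis_iv[[cid]][2],
          stringsAsFactors = FALSE))
      }
      if (length(dup_iv) == 2L) {
        truth_dup <- rbind(truth_dup, data.frame(
          species = sp, gene_id = gid,
          intron_ordinal = dup_slot$intron,
          a_start = dup_iv$dupA[1], a_end = dup_iv$dupA[2],
          b_start = dup_iv$dupB[1], b_end = dup_iv$dupB[2],
          stringsAsFactors = FALSE))
      }
    }
  }

  truth <- list(cis = truth_cis, duplication = truth_dup,
                stop_skip = truth_stop, frameshift = truth_fs,
                exonized = truth_exo)
  out <- list(genes = genes, truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sp in species) {
      write_gene_models(genes[[sp]],
                        file.path(out_dir, paste0(sp, ".gff3")),
                        file.path(out_dir, paste0(sp, ".fa")))
    }
    bed <- truth_cis[truth_cis$species == species[1L], , drop = FALSE]
    writeLines(c("# planted CIS truth (anchor species)",
                 sprintf("%s\t%d\t%d\t%s:%d:%s\t0\t+", bed$gene_id,
                         bed$start, bed$end, bed$gene_id,
                         bed$intron_ordinal, bed$cis_id)),
               file.path(out_dir, "truth.bed"))
    manifest <- unclass(config)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
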