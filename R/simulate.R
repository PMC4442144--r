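# Synthetic-data generator emulating the published control experiments:
# gene models with tunable inter-variant similarity, isoform mixtures at
# fixed ratios, ligation products with template-switch and near-cognate
# artifact modes, and 250-nt paired-end reads with overlapping 3' ends.

#' Synthesize a gene model with tunable variant similarity
#'
#' Builds a model of `n_clusters` mutually exclusive cassette clusters
#' separated (and flanked) by constitutive blocks. Within a cluster, a
#' fraction `similarity` of positions is conserved across all variants
#' (copied from a cluster consensus); the remaining positions are drawn
#' independently per variant, so the expected pairwise identity is
#' `similarity + (1 - similarity)/4` (0.25 at `similarity = 0`, the random
#' expectation; 1 at `similarity = 1`).
#'
#' @param n_clusters Number of cassette clusters.
#' @param variants_per_cluster Integer (recycled) or vector of cluster sizes.
#' @param exon_length Variant exon length in nt.
#' @param similarity Fraction of conserved positions within a cluster, in
#'   \[0, 1\].
#' @param seed Integer seed; the model is reproducible under it.
#' @param flank_length Length of the terminal and inter-cluster
#'   constitutive blocks.
#' @param gene_id Gene identifier.
#' @param cluster_ids Optional cluster region ids (default `c1`, `c2`, ...);
#'   variant ids are `<cluster>.<j>`.
#' @return A [gene_model()].
#' @export
#' @examples
#' gm <- synth_gene(2, 3, exon_length = 60, similarity = 0.5, seed = 1)
#' enumerate_isoforms(gm)
synth_gene <- function(n_clusters, variants_per_cluster, exon_length = 150,
                       similarity = 0.75, seed = 1L, flank_length = 150,
                       gene_id = "synth", cluster_ids = NULL) {
  stopifnot(similarity >= 0, similarity <= 1, n_clusters >= 1)
  sizes <- rep_len(variants_per_cluster, n_clusters)
  if (is.null(cluster_ids)) cluster_ids <- paste0("c", seq_len(n_clusters))
  n_free <- exon_length - round(similarity * exon_length)
  if (any(sizes > 1) && similarity < 1 && 4^n_free < 100 * max(sizes))
    abort("exon_length too short to make this many distinguishable variants at this similarity",
          class = "ligzip_error_sim")
  bases <- c("A", "C", "G", "T")
  # region termini are drawn GC-biased (60%) so that splint arms in the
  # 55-65 C window exist at 12-25 nt, as at designable target sites;
  # interiors are uniform
  draw_masked <- function(gc_mask) {
    v <- character(length(gc_mask))
    v[gc_mask] <- sample(bases, sum(gc_mask), replace = TRUE,
                         prob = c(0.2, 0.3, 0.3, 0.2))
    v[!gc_mask] <- sample(bases, sum(!gc_mask), replace = TRUE)
    v
  }
  draw_seq <- function(len, edge = 20L) {
    draw_masked(seq_len(len) <= edge | seq_len(len) > len - edge)
  }
  rand_seq <- function(n) paste(draw_seq(n), collapse = "")
  with_seed(seed, {
    regions <- list(list(id = "flank5", type = "constitutive",
                         sequence = rand_seq(flank_length)))
    for (k in seq_len(n_clusters)) {
      gc_mask <- seq_len(exon_length) <= 20L |
        seq_len(exon_length) > exon_length - 20L
      consensus <- draw_seq(exon_length)
      conserved <- sample.int(exon_length, round(similarity * exon_length))
      repeat {
        vs <- vapply(seq_len(sizes[k]), function(j) {
          v <- draw_masked(gc_mask)
          v[conserved] <- consensus[conserved]
          paste(v, collapse = "")
        }, character(1))
        if (!anyDuplicated(vs) || similarity == 1) break
      }
      names(vs) <- paste0(cluster_ids[k], ".", seq_len(sizes[k]))
      regions[[length(regions) + 1L]] <-
        list(id = cluster_ids[k], type = "cassette", variants = vs)
      regions[[length(regions) + 1L]] <- list(
        id = if (k < n_clusters) paste0("b", k) else "flank3",
        type = "constitutive", sequence = rand_seq(flank_length))
    }
    gene_model(gene_id, regions)
  })
}

#' Draw molecules from an isoform mixture
#'
#' Multinomial sample of `n_molecules` molecules over isoform keys with the
#' given relative weights (e.g. `c(a = 100, b = 10, c = 1)` for a 100:10:1
#' mixture).
#'
#' @param gm A [gene_model()].
#' @param proportions Named nonnegative weights over isoform keys (need not
#'   sum to 1).
#' @param n_molecules Number of molecules.
#' @param seed Integer seed.
#' @return A tibble (`molecule_id`, `isoform_key`).
#' @export
simulate_isoform_mix <- function(gm, proportions, n_molecules, seed = 1L) {
  keys <- enumerate_isoforms(gm)
  if (is.null(names(proportions)) || !all(names(proportions) %in% keys))
    abort("`proportions` must be named by isoform keys of the model",
          class = "ligzip_error_sim")
  if (any(proportions < 0) || sum(proportions) <= 0)
    abort("`proportions` must be nonnegative and not all zero",
          class = "ligzip_error_sim")
  with_seed(seed, {
    draws <- sample(names(proportions), n_molecules, replace = TRUE,
                    prob = proportions)
    tibble(molecule_id = sprintf("mol%06d", seq_len(n_molecules)),
           isoform_key = draws)
  })
}

# nearest near-cognate ligamer for every variant ligamer of a pool:
# the same-cluster ligamer with the smallest delta-G gap on its own exon
nearest_near_cognates <- function(pool, gm, params = duplex_params()) {
  vl <- dplyr::filter(pool, !is.na(.data$variant_id))
  if (nrow(vl) == 0) return(stats::setNames(character(0), character(0)))
  out <- vapply(seq_len(nrow(vl)), function(i) {
    lg <- vl[i, ]
    sibs <- dplyr::filter(vl, .data$region_id == lg$region_id,
                          .data$variant_id != lg$variant_id)
    if (nrow(sibs) == 0) return(NA_character_)
    target <- region_variant_seq(gm, lg$region_id, lg$variant_id)
    gaps <- vapply(seq_len(nrow(sibs)), function(j) {
      sb <- sibs[j, ]
      lu <- nchar(sb$arm_up); ld <- nchar(sb$arm_down)
      if (nchar(target) < max(lu, ld)) return(Inf)
      duplex_free_energy(reverse_complement(sb$arm_up),
                         substr(target, 1, lu), params) +
        duplex_free_energy(reverse_complement(sb$arm_down),
                           substring(target, nchar(target) - ld + 1, nchar(target)),
                           params)
    }, numeric(1))
    sibs$ligamer_id[which.min(gaps)]
  }, character(1))
  stats::setNames(out, vl$ligamer_id)
}

#' Simulate ligation products with artifact modes
#'
#' Each molecule yields one ligation product. With probability
#' `switch_rate` the product is chimeric: a crossover at a uniformly chosen
#' internal junction joins the 5' chain of the molecule to the 3' chain of
#' another molecule (drawn from the other pool when two pools are supplied,
#' mirroring dual-coded control reactions). With probability
#' `near_cognate_rate` one variant ligamer of the chain is replaced by its
#' nearest near-cognate ligamer (smallest free-energy gap on the true
#' exon); the resulting product is sequence-identical to a genuine product
#' of the wrong isoform, which is why such events need control mixtures to
#' be measured. The truth ledger records every event.
#'
#' @param molecules Tibble from [simulate_isoform_mix()].
#' @param pools A single `ligamer_pool` or a list of two differentially
#'   coded pools from [plan_dual_pools()].
#' @param gm The [gene_model()].
#' @param switch_rate,near_cognate_rate Artifact probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @return A tibble of class `truth_ledger`: `product_id`, `molecule_id`,
#'   `true_isoform_key`, `pool_label`, `artifact` (one of `cognate`,
#'   `near_cognate`, `switched`), `partner_key`, `sequence`.
#' @export
simulate_ligation <- function(molecules, pools, gm, switch_rate = 0,
                              near_cognate_rate = 0, seed = 1L) {
  stopifnot(switch_rate >= 0, switch_rate <= 1,
            near_cognate_rate >= 0, near_cognate_rate <= 1)
  if (inherits(pools, "ligamer_pool")) pools <- list(pools)
  labels <- vapply(pools, function(p) p$pool_label[1], character(1))
  idx <- lapply(pools, function(p) build_product_index(gm, p))
  chain_of <- lapply(idx, function(ix)
    stats::setNames(ix$ligamer_chain, ix$isoform_key))
  seq_of_lig <- lapply(pools, function(p)
    stats::setNames(p$sequence, p$ligamer_id))
  bc_of <- lapply(pools, function(p)
    stats::setNames(!is.na(p$barcode), p$ligamer_id))
  nnc <- lapply(pools, function(p) nearest_near_cognates(p, gm))
  n <- nrow(molecules)
  with_seed(seed, {
    pool_i <- if (length(pools) == 2) sample(c(1L, 2L), n, replace = TRUE)
    else rep(1L, n)
    u_switch <- stats::runif(n) < switch_rate
    u_nc <- !u_switch & (stats::runif(n) < near_cognate_rate)
    chains <- purrr::map(seq_len(n), function(i)
      chain_of[[pool_i[i]]][[molecules$isoform_key[i]]])
    partner_key <- rep(NA_character_, n)
    artifact <- rep("cognate", n)
    for (i in which(u_switch)) {
      # partner from the other pool when dual-coded, else any other molecule
      cand <- if (length(pools) == 2) which(pool_i != pool_i[i]) else
        setdiff(seq_len(n), i)
      if (length(cand) == 0) next
      j <- cand[sample.int(length(cand), 1)]
      own <- chains[[i]]
      other <- chain_of[[pool_i[j]]][[molecules$isoform_key[j]]]
      if (length(own) < 2 || length(other) < 2) next
      # crossover junctions must leave a barcoded ligamer on each side, so
      # that the chimera carries both codings (unbarcoded-junction switches
      # would be invisible to any decoder and are not modeled)
      own_bc <- which(bc_of[[pool_i[i]]][own])
      other_bc <- which(bc_of[[pool_i[j]]][other])
      if (length(own_bc) == 0 || length(other_bc) == 0) next
      feas <- seq_len(length(own) - 1L)
      feas <- feas[feas >= min(own_bc) &
                     pmin(feas, length(other) - 1L) < max(other_bc)]
      if (length(feas) == 0) next
      k <- feas[sample.int(length(feas), 1)]
      k2 <- min(k, length(other) - 1L)
      chains[[i]] <- c(own[seq_len(k)], other[(k2 + 1L):length(other)])
      # the suffix ligamers come from the partner's pool
      attr(chains[[i]], "suffix_pool") <- pool_i[j]
      attr(chains[[i]], "suffix_from") <- k + 1L
      partner_key[i] <- molecules$isoform_key[j]
      artifact[i] <- "switched"
    }
    for (i in which(u_nc)) {
      ch <- chains[[i]]
      repl <- nnc[[pool_i[i]]][ch]
      repl <- repl[!is.na(repl)]
      if (length(repl) == 0) next
      pos <- sample.int(length(repl), 1)
      ch[match(names(repl)[pos], ch)] <- repl[[pos]]
      chains[[i]] <- ch
      artifact[i] <- "near_cognate"
    }
    seqs <- vapply(seq_len(n), function(i) {
      ch <- chains[[i]]
      sp <- attr(ch, "suffix_pool")
      if (is.null(sp)) paste(seq_of_lig[[pool_i[i]]][ch], collapse = "")
      else {
        from <- attr(ch, "suffix_from")
        paste(c(seq_of_lig[[pool_i[i]]][ch[seq_len(from - 1L)]],
                seq_of_lig[[sp]][ch[from:length(ch)]]),
              collapse = "")
      }
    }, character(1))
    out <- tibble(
      product_id = sprintf("prod%06d", seq_len(n)),
      molecule_id = molecules$molecule_id,
      true_isoform_key = molecules$isoform_key,
      pool_label = labels[pool_i],
      artifact = artifact,
      partner_key = partner_key,
      sequence = seqs
    )
    structure(out, class = c("truth_ledger", class(out)))
  })
}

#' Simulate paired-end reads from ligation products
#'
#' Read 1 is the 5' prefix of the product, read 2 the reverse complement of
#' its 3' suffix, each `min(read_length, product length)` nt, so mates of
#' products shorter than twice the read length overlap at their 3' ends.
#' Substitution errors are i.i.d. at `per_base_error`; qualities are
#' constant; no indels.
#'
#' @param products A `truth_ledger` (or any tibble with `product_id`,
#'   `sequence`).
#' @param read_length Read length in nt (default 250, paired).
#' @param per_base_error Per-base substitution probability.
#' @param seed Integer seed; identical inputs give byte-identical FASTQ.
#' @return A tibble (`read_id`, `product_id`, `r1`, `r2`).
#' @export
simulate_reads <- function(products, read_length = 250, per_base_error = 0,
                           seed = 1L) {
  if (nrow(products) == 0)
    abort("empty product set", class = "ligzip_error_sim")
  len <- nchar(products$sequence)
  if (any(len >= 2 * read_length))
    warn("some products are not shorter than twice the read length; their mates will not overlap")
  r1 <- substr(products$sequence, 1, pmin(read_length, len))
  r2 <- reverse_complement(
    substring(products$sequence, pmax(1, len - read_length + 1), len))
  with_seed(seed, {
    if (per_base_error > 0) {
      r1 <- mutate_reads(r1, per_base_error)
      r2 <- mutate_reads(r2, per_base_error)
    }
    tibble(read_id = paste0("read_", products$product_id),
           product_id = products$product_id, r1 = r1, r2 = r2)
  })
}

# i.i.d. substitutions at rate p; substituted base drawn from the other 3
mutate_reads <- function(reads, p) {
  bases <- c("A", "C", "G", "T")
  n_err <- stats::rbinom(length(reads), nchar(reads), p)
  hit <- which(n_err > 0)
  for (i in hit) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(ch), n_err[i])
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(bases, b), 1), character(1))
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Write / read a read pair as two FASTQ files
#'
#' @param reads Tibble from [simulate_reads()].
#' @param r1_path,r2_path Output FASTQ paths.
#' @param quality_char Constant quality character.
#' @return `write_fastq_pair()` returns the paths invisibly;
#'   `read_fastq_pair()` returns a tibble (`read_id`, `r1`, `r2`).
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path, quality_char = "I") {
  wr <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
    q <- Biostrings::BStringSet(strrep(quality_char, nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  wr(reads$r1, reads$read_id, r1_path)
  wr(reads$r2, reads$read_id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' @rdname write_fastq_pair
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  x1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  x2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (!identical(names(x1), names(x2)))
    abort("mate files are not in the same read order", class = "ligzip_error_io")
  tibble(read_id = names(x1), r1 = unname(as.character(x1)), r2 = unname(as.character(x2)))
}

#' Write a truth ledger as TSV
#'
#' @param ledger A `truth_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(ledger, path) {
  utils::write.table(as.data.frame(ledger), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
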