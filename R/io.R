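#' Read per-genome protein FASTA files
#'
#' One genome per FASTA file; the genome id is the file stem. Record ids
#' (the first whitespace-delimited token of each header) are the gene ids
#' and must be unique within a genome. Empty files are skipped with a
#' warning.
#'
#' @param directory Directory containing `.faa`/`.fa`/`.fasta` files.
#' @return Named list of `AAStringSet` (class `genome_set`).
#' @export
read_genomes <- function(directory) {
  stopifnot(dir.exists(directory))
  files <- list.files(directory, pattern = "\\.(faa|fa|fasta)$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no FASTA files in ", directory)
  out <- list()
  for (f in sort(files)) {
    gid <- sub("\\.[^.]*$", "", basename(f))
    ss <- Biostrings::readAAStringSet(f)
    if (length(ss) == 0) {
      warning("empty FASTA skipped: ", f)
      next
    }
    names(ss) <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(names(ss))) {
      dup <- names(ss)[duplicated(names(ss))][1]
      stop("duplicate gene id '", dup, "' in ", f)
    }
    out[[gid]] <- ss
  }
  structure(out, class = "genome_set")
}

#' Write a genome set as per-genome FASTA files
#'
#' @param genomes Named list of `AAStringSet`.
#' @param directory Output directory (created if needed).
#' @return Written paths, invisibly.
#' @export
write_genomes <- function(genomes, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- vapply(names(genomes), function(g) {
    p <- file.path(directory, paste0(g, ".faa"))
    Biostrings::writeXStringSet(genomes[[g]], p)
    p
  }, "")
  invisible(paths)
}

#' Pipeline configuration
#'
#' Collects the paths and stage parameters of a full run. Numeric defaults
#' are the published ones: 10 rarefaction replicates, FBH thresholds
#' e-value 1e-20 / coverage 30% / similarity 60%, gain:loss costs 2:1, and
#' core-fit initial guesses (1, 1, 0.1, 0.1, 1500). Every referenced path
#' must exist when the config is built.
#'
#' @param genome_dir Directory of per-genome protein FASTA files.
#' @param out_dir Output directory.
#' @param tree_file Optional rooted newick whose tips match the genome ids
#'   (enables the gain/loss stage).
#' @param hits_file Optional precomputed BLAST tabular hits (takes
#'   precedence over the built-in aligner).
#' @param reference_fasta,reference_categories Optional screen reference
#'   FASTA and `ref_id`/`category` TSV (enable the screen stage).
#' @param annotations_file Optional `gene_id`/`category` TSV for the COG
#'   distribution stage.
#' @param groups Optional named character vector mapping genome id to a
#'   group label (e.g. pigmented / non-pigmented).
#' @param replicates,seed,costs,screen Stage parameters.
#' @param skip Character vector of stages to skip, among
#'   `c("rarefaction", "fits", "ancestral", "screens")`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_dir, out_dir,
                            tree_file = NULL, hits_file = NULL,
                            reference_fasta = NULL,
                            reference_categories = NULL,
                            annotations_file = NULL,
                            groups = NULL,
                            replicates = 10L, seed = 1L,
                            costs = cost_scheme(),
                            screen = screen_config("mobilome"),
                            skip = character(0)) {
  for (p in c(genome_dir, tree_file, hits_file, reference_fasta,
              reference_categories, annotations_file)) {
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  }
  stopifnot(all(skip %in% c("rarefaction", "fits", "ancestral", "screens")))
  structure(list(genome_dir = genome_dir, out_dir = out_dir,
                 tree_file = tree_file, hits_file = hits_file,
                 reference_fasta = reference_fasta,
                 reference_categories = reference_categories,
                 annotations_file = annotations_file, groups = groups,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), costs = costs, screen = screen,
                 skip = skip),
            class = "pipeline_config")
}

#' Run the full pangenome-evolution pipeline
#'
#' Executes orthology clustering, pangenome partitioning, rarefaction,
#' curve fits, gain/loss reconstruction and the mobilome screen in order,
#' writing each stage's TSV output and a run manifest to the output
#' directory. Stages whose inputs are absent (no tree, no reference) or
#' that are listed in `skip` are omitted; a failed stage is recorded in
#' the manifest and downstream stages are not run. Identical config and
#' seed reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- data.frame(stage = character(0), status = character(0),
                         detail = character(0))
  note <- function(stage, status, detail = "") {
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, status = status,
                                  detail = detail))
  }
  results <- list()
  fail <- function(stage, e) {
    note(stage, "failed", conditionMessage(e))
    write_tsv_hash(manifest, file.path(out_dir, "manifest.tsv"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  genomes <- tryCatch(read_genomes(config$genome_dir),
                      error = function(e) fail("read_genomes", e))
  note("read_genomes", "ok", paste(length(genomes), "genomes"))

  clustering <- tryCatch({
    hits <- if (!is.null(config$hits_file)) {
      read_blast_tab(config$hits_file, genomes)
    } else NULL
    cluster_genomes(genomes, hits)
  }, error = function(e) fail("orthology", e))
  write_tsv_hash(clustering$families, file.path(out_dir, "families.tsv"))
  mat <- clustering$matrix
  write_tsv_hash(data.frame(family_id = rownames(mat),
                            as.data.frame(mat), check.names = FALSE),
                 file.path(out_dir, "presence_matrix.tsv"))
  note("orthology", "ok", paste(nrow(mat), "families"))
  results$clustering <- clustering

  part <- pangenome_partition(mat)
  write_tsv_hash(data.frame(section = names(part$counts),
                            count = as.integer(part$counts),
                            percent = as.integer(part$percent)),
                 file.path(out_dir, "partition.tsv"))
  note("partition", "ok", paste(part$total, "families"))
  results$partition <- part

  if (!is.null(config$annotations_file)) {
    ann <- read_tsv_hash(config$annotations_file)
    dist <- category_distribution(clustering$families, part, ann)
    write_tsv_hash(dist, file.path(out_dir, "category_distribution.tsv"))
    note("categories", "ok")
    results$categories <- dist
  }

  if (!"rarefaction" %in% config$skip) {
    tab <- tryCatch(rarefy(mat, replicates = config$replicates,
                           seed = derive_seed(config$seed, "rarefaction")),
                    error = function(e) fail("rarefaction", e))
    write_tsv_hash(as.data.frame(tab), file.path(out_dir, "rarefaction.tsv"))
    note("rarefaction", "ok", paste(nrow(tab), "rows"))
    results$rarefaction <- tab

    if (!"fits" %in% config$skip) {
      fits <- tryCatch({
        f <- list(heap = fit_heap(tab), decay = fit_new_gene_decay(tab))
        # the double exponential has 5 free parameters and needs >= 6
        # distinct N values (i.e. at least 7 genomes)
        if (length(unique(tab$n[!tab$extended])) >= 6) {
          f$core <- fit_core_decay(tab)
        }
        f
      }, error = function(e) fail("fits", e))
      fits$openness <- classify_openness(fits$heap)
      fit_rows <- do.call(rbind, lapply(
        Filter(Negate(is.null), fits[intersect(c("heap", "decay", "core"),
                                               names(fits))]),
        function(f) data.frame(model = f$model,
                               parameter = names(f$parameters),
                               value = unname(f$parameters),
                               rss = f$residual_sum_of_squares,
                               converged = f$converged)))
      write_tsv_hash(fit_rows, file.path(out_dir, "fits.tsv"))
      note("fits", "ok", paste0("gamma=", signif(fits$openness$gamma, 4),
                                " (", fits$openness$status, ")"))
      results$fits <- fits
    }
  }

  if (!is.null(config$tree_file) && !"ancestral" %in% config$skip) {
    recon <- tryCatch({
      tree <- ape::read.tree(config$tree_file)
      reconstruct_gain_loss(mat, tree, config$costs)
    }, error = function(e) fail("ancestral", e))
    write_tsv_hash(ancestral_size_profile(recon),
                   file.path(out_dir, "ancestral_sizes.tsv"))
    write_tsv_hash(recon$edges, file.path(out_dir, "branch_events.tsv"))
    write_annotated_tree(recon, file.path(out_dir, "annotated_tree.nwk"))
    note("ancestral", "ok",
         paste("LCA size", recon$node_sizes[length(recon$tree$tip.label) + 1]))
    results$ancestral <- recon
  }

  if (!is.null(config$reference_fasta) && !"screens" %in% config$skip) {
    screen <- tryCatch({
      ref <- Biostrings::readAAStringSet(config$reference_fasta)
      names(ref) <- sub("\\s.*$", "", names(ref))
      cats <- read_tsv_hash(config$reference_categories)
      fbh_screen(genomes, ref, cats, config$screen)
    }, error = function(e) fail("screens", e))
    write_tsv_hash(screen$assignments, file.path(out_dir, "screen_hits.tsv"))
    write_tsv_hash(screen$counts, file.path(out_dir, "screen_counts.tsv"))
    mob <- tryCatch(panmobilome(clustering$families, mat, screen),
                    error = function(e) NULL)
    if (!is.null(mob)) {
      write_tsv_hash(data.frame(section = names(mob$counts),
                                count = as.integer(mob$counts)),
                     file.path(out_dir, "panmobilome.tsv"))
    }
    note("screens", "ok", paste(sum(screen$assignments$pass), "genes assigned"))
    results$screen <- screen
    results$panmobilome <- mob
  }

  manifest <- rbind(manifest,
                    data.frame(stage = "seed", status = "info",
                               detail = as.character(config$seed)))
  write_tsv_hash(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(results)
}
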