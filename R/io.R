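# File formats and run plumbing: TSV well tables with the 27-column
# feature schema, plate layouts, annotation and edge-list readers, Newick
# tree output with node labels, JSON reports and YAML-compatible configs.

#' Write per-cell well tables, one TSV per slide
#'
#' @param screen A `primary_screen` (or list with `cells`).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_well_tables <- function(screen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cells <- screen$cells
  paths <- vapply(unique(cells$slide), function(sl) {
    p <- file.path(dir, paste0("wells_", sl, ".tsv"))
    write.table(cells[cells$slide == sl, , drop = FALSE], p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read and validate per-cell well tables
#'
#' Requires the well metadata columns and all 27 feature columns; unknown
#' columns are preserved as passthrough. Wells with no cells are kept and
#' flagged.
#'
#' @param paths TSV file paths (as written by [write_well_tables()]).
#' @return List with `cells` (validated data frame) and `layout`
#'   (well-level metadata with `n_cells`, flagging `low_cell` wells).
#' @export
read_well_tables <- function(paths) {
  req_meta <- c("well_id", "slide", "row", "col", "role", "gene",
                "replicate", "cell_id")
  tabs <- lapply(paths, function(p) {
    tab <- read.delim(p, sep = "\t", stringsAsFactors = FALSE)
    missing_f <- setdiff(feature_catalog(), colnames(tab))
    if (length(missing_f))
      stopf("%s: missing feature %s", basename(p), missing_f[1])
    missing_m <- setdiff(req_meta, colnames(tab))
    if (length(missing_m))
      stopf("%s: missing column %s", basename(p), missing_m[1])
    for (f in feature_catalog()) {
      bad <- which(!is.na(tab[[f]]) & is.na(suppressWarnings(
        as.numeric(tab[[f]]))))
      if (length(bad))
        stopf("%s: non-numeric value in column %s, row %d", basename(p),
              f, bad[1])
      tab[[f]] <- as.numeric(tab[[f]])
    }
    tab
  })
  cells <- do.call(rbind, tabs)
  rownames(cells) <- NULL
  layout <- unique(cells[, c("well_id", "slide", "row", "col", "role",
                             "gene", "replicate")])
  rownames(layout) <- NULL
  counts <- table(cells$well_id)
  layout$n_cells <- as.integer(counts[layout$well_id])
  layout$low_cell <- layout$n_cells < 50
  list(cells = cells, layout = layout)
}

#' Read a gene-to-term annotation table
#'
#' Accepts a two-column TSV (gene, GO id; header optional) or a GAF 2.x
#' file (gene from column 2, term from column 5, comment lines starting
#' with `!`).
#'
#' @param path File path.
#' @param format `"tsv"` or `"gaf"`.
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "gaf") {
    tab <- read.delim(path, header = FALSE, comment.char = "!",
                      stringsAsFactors = FALSE)
    ann <- data.frame(gene = tab[[2]], term = tab[[5]])
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(as.character(tab[1, 1])), "gene"))
      tab <- tab[-1, , drop = FALSE]
    ann <- data.frame(gene = tab[[1]], term = tab[[2]])
  }
  annotation_map(ann)
}

#' Read a weighted interaction edge list (TSV: geneA, geneB, confidence)
#' @param path File path (header optional).
#' @return Edge-list data frame (`a`, `b`, `confidence`).
#' @export
read_edge_list <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (is.na(suppressWarnings(as.numeric(tab[1, 3]))))
    tab <- tab[-1, , drop = FALSE]
  data.frame(a = as.character(tab[[1]]), b = as.character(tab[[2]]),
             confidence = as.numeric(tab[[3]]))
}

#' Write a feature tree as Newick plus a node-membership table
#'
#' The Newick string carries internal node labels (`node1`...) and, when
#' present, jackknife support as `nodeN|support`; the companion TSV lists
#' one row per (node, gene, event).
#'
#' @param ft A `feature_tree` (from [assign_characters()]) or a `phylo`.
#' @param path Base path; writes `<path>.nwk` and, for feature trees,
#'   `<path>_members.tsv`.
#' @return Invisibly, the written paths.
#' @export
write_tree <- function(ft, path) {
  if (inherits(ft, "feature_tree")) {
    phy <- ft$tree
    if (!is.null(ft$support) && !all(is.na(ft$support))) {
      sup <- rep(NA_real_, phy$Nnode)
      sup[seq_along(ft$support)] <- ft$support
      phy$node.label <- ifelse(is.na(sup), phy$node.label,
                               paste0(phy$node.label, "|", sup))
    }
    nwk <- paste0(path, ".nwk")
    ape::write.tree(phy, file = nwk)
    mem <- paste0(path, "_members.tsv")
    write.table(ft$events, mem, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(c(nwk, mem)))
  }
  nwk <- paste0(path, ".nwk")
  ape::write.tree(ft, file = nwk)
  invisible(nwk)
}

#' Read a Newick tree written by [write_tree()]
#' @param path Path to the `.nwk` file.
#' @return An `ape::phylo`; support values split out of the node labels
#'   into `tree$support`.
#' @export
read_tree <- function(path) {
  phy <- ape::read.tree(path)
  if (!is.null(phy$node.label) && any(grepl("\\|", phy$node.label))) {
    parts <- strsplit(phy$node.label, "\\|")
    phy$support <- suppressWarnings(
      as.numeric(vapply(parts, function(x) x[2] %||% NA_character_, "")))
    phy$node.label <- vapply(parts, `[`, "", 1)
  }
  phy
}

#' Write/read a screen configuration as YAML
#' @param config A [screen_config()].
#' @param path Output path.
#' @return `write_config`: invisibly, the path. `read_config`: the config.
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  lst$effect_table <- if (nrow(lst$effect_table))
    as.list(as.data.frame(lst$effect_table)) else NULL
  lst$baseline <- as.list(lst$baseline)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  eff <- if (!is.null(lst$effect_table))
    as.data.frame(lst$effect_table, stringsAsFactors = FALSE) else NULL
  screen_config(n_genes = lst$n_genes, n_replicates = lst$n_replicates,
                n_rows = lst$n_rows, n_cols = lst$n_cols,
                n_negative = lst$n_negative, n_positive = lst$n_positive,
                cells_per_well = lst$cells_per_well,
                artifact = lst$artifact, effect_table = eff,
                positive_effect = lst$positive_effect, seed = lst$seed)
}

#' Run manifest for a pipeline invocation
#'
#' Records the configuration digest, seed, package version and input-file
#' digests so that a deterministic stage can be re-run bit-identically.
#'
#' @param config A [screen_config()] (or any serializable list).
#' @param seed Seed used for the run.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, inputs = character()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  structure(list(
    config_hash = unname(tools::md5sum(tmp)),
    seed = seed,
    package_version = as.character(utils::packageVersion("endoscreen")),
    input_digests = if (length(inputs)) tools::md5sum(inputs) else NULL,
    timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_manifest")
}

#' Run the primary pipeline end to end
#'
#' simulate -> Z-score -> call hits -> build tree, writing every
#' intermediate artifact plus a JSON manifest to `out_dir`. Each stage is
#' re-runnable from the on-disk intermediates through the corresponding
#' reader.
#'
#' @param config A [screen_config()].
#' @param out_dir Output directory.
#' @param threshold,min_reps Hit rule.
#' @param n_jackknife,n_restarts Tree search effort.
#' @param seed Seed for scoring/tree stages.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_primary_pipeline <- function(config, out_dir, threshold = 3,
                                 min_reps = 2, n_jackknife = 100,
                                 n_restarts = 25, seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  scr <- generate_primary_screen(config)
  write_well_tables(scr, file.path(out_dir, "wells"))
  z <- zscore_screen(scr, seed = seed)
  write.table(z$scores, file.path(out_dir, "zscores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  zm <- zscore_matrix(z)
  hits <- call_hits(zm, threshold = threshold, min_reps = min_reps)
  fv <- binarize(hits)
  write.table(fv, file.path(out_dir, "feature_vectors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  result <- list(screen = scr, zscores = z, hits = hits, fv = fv)
  cm <- tryCatch(filter_nontrivial(fv[fv$is_hit, , drop = FALSE]),
                 error = function(e) NULL)
  if (!is.null(cm) && ncol(cm) >= 4) {
    jc <- jackknife_consensus(cm, n_reps = n_jackknife,
                              n_restarts = n_restarts, seed = seed)
    ft <- assign_characters(jc$tree, cm)
    write_tree(ft, file.path(out_dir, "feature_tree"))
    result$tree <- ft
  }
  manifest <- run_manifest(config, seed)
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}
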