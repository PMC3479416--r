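# End-to-end orchestration: manifest of bound/unbound structures ->
# per-residue records (surface class + chi vector) -> four-category
# DADF comparison tables and critical-spacing summary.

#' Analysis configuration
#'
#' @param spacings grid spacings scanned, degrees.
#' @param n_repeats random split origins per comparison.
#' @param probe,n_points SASA parameters (see [sasa_atoms()]).
#' @param rel_min relative-SASA surface threshold (fraction).
#' @param dsasa_min interface threshold on SASA loss (Angstrom^2).
#' @param r_threshold correlation level for the critical spacing.
#' @param min_samples smallest pool size admitted to a comparison.
#' @param min_identity bound/unbound identity warning threshold.
#' @param seed optional integer seed for [run_analysis()].
#' @return a named list.
#' @export
chigrid_config <- function(spacings = c(10, 20, 30, 40, 50, 60, 70, 80, 90),
                           n_repeats = 100, probe = 1.4, n_points = 960,
                           rel_min = 0.25, dsasa_min = 1.0,
                           r_threshold = 0.7, min_samples = 20,
                           min_identity = 0.97, seed = NULL) {
  list(spacings = spacings, n_repeats = n_repeats, probe = probe,
       n_points = n_points, rel_min = rel_min, dsasa_min = dsasa_min,
       r_threshold = r_threshold, min_samples = min_samples,
       min_identity = min_identity, seed = seed)
}

#' Read a case manifest
#'
#' Tab-separated with columns `case_id`, `complex_pdb`,
#' `receptor_chains`, `ligand_chains`, `unbound_receptor_pdb`,
#' `unbound_receptor_chains`, `unbound_ligand_pdb`,
#' `unbound_ligand_chains`; chain sets are comma- or juxtaposition-free
#' strings of single-character ids (e.g. `"AB"`), empty fields allowed
#' for missing unbound structures. Relative paths are resolved against
#' the manifest's directory.
#'
#' @param file manifest path.
#' @return data.frame, one row per case.
#' @export
read_manifest <- function(file) {
  mf <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          colClasses = "character")
  need <- c("case_id", "complex_pdb", "receptor_chains", "ligand_chains",
            "unbound_receptor_pdb", "unbound_receptor_chains",
            "unbound_ligand_pdb", "unbound_ligand_chains")
  missing <- setdiff(need, names(mf))
  if (length(missing) > 0L)
    stopf("manifest lacks column(s): %s", paste(missing, collapse = ", "))
  base <- dirname(file)
  for (col in c("complex_pdb", "unbound_receptor_pdb", "unbound_ligand_pdb")) {
    rel <- !is.na(mf[[col]]) & !grepl("^(/|[A-Za-z]:)", mf[[col]])
    mf[[col]][rel] <- file.path(base, mf[[col]][rel])
  }
  mf
}

split_chains <- function(x) {
  if (is.na(x) || x == "") return(character(0))
  strsplit(gsub("[ ,]", "", x), "")[[1]]
}

# classify + chi for one bound monomer and its optional unbound partner
process_side <- function(cplx, side_chains, unbound_file, unbound_chains,
                         case_id, side, config) {
  mono <- extract_monomer(cplx, side_chains)
  sasa_mono <- sasa_residues(mono, sasa_atoms(mono, config$probe,
                                              config$n_points))
  sasa_cplx_all <- sasa_residues(cplx, sasa_atoms(cplx, config$probe,
                                                  config$n_points))
  sasa_cplx <- sasa_cplx_all[match(sasa_mono$res_key, sasa_cplx_all$res_key), ]
  dsasa <- delta_sasa(sasa_mono$abs_sasa, sasa_cplx$abs_sasa)
  keep <- sasa_mono$res_type %in% AA3
  rel_bound <- rep(NA_real_, nrow(sasa_mono))
  rel_bound[keep] <- relative_sasa(sasa_mono$abs_sasa[keep],
                                   sasa_mono$res_type[keep])

  unbound <- NULL
  rel_unbound <- rep(NA_real_, nrow(sasa_mono))
  corr_map <- NULL
  if (!is.null(unbound_file) && !is.na(unbound_file)) {
    unbound <- read_structure(unbound_file, unbound_chains)
    sasa_unb <- sasa_residues(unbound, sasa_atoms(unbound, config$probe,
                                                  config$n_points))
    pairs_all <- list()
    for (k in seq_along(side_chains)) {
      corr <- map_residues(mono, side_chains[k], unbound,
                           unbound_chains[k],
                           min_identity = config$min_identity)
      pairs_all[[k]] <- corr$pairs
    }
    corr_map <- do.call(rbind, pairs_all)
    hit <- match(sasa_mono$res_key, corr_map$bound_key)
    unb_key <- corr_map$unbound_key[hit]
    uhit <- match(unb_key, sasa_unb$res_key)
    ok <- !is.na(uhit) & sasa_unb$res_type[pmax(uhit, 1L)] %in% AA3
    rel_unbound[ok] <- relative_sasa(sasa_unb$abs_sasa[uhit[ok]],
                                     sasa_unb$res_type[uhit[ok]])
  }

  cls <- rep("excluded", nrow(sasa_mono))
  cls[keep] <- classify_surface(rel_bound[keep], rel_unbound[keep],
                                dsasa[keep], config$rel_min,
                                config$dsasa_min)

  chi_bound <- chi_angles(mono)
  stopifnot(identical(chi_bound$res_key, sasa_mono$res_key))
  rec <- data.frame(
    case_id = case_id, side = side, state = "bound",
    chi_bound[, c("res_key", "res_type",
                  paste0("chi", 1:4), "n_chi", "complete")],
    class = cls, stringsAsFactors = FALSE
  )

  if (!is.null(unbound)) {
    chi_unb <- chi_angles(unbound)
    hit <- match(chi_unb$res_key, corr_map$unbound_key)
    bkey <- corr_map$bound_key[hit]
    bcls <- cls[match(bkey, sasa_mono$res_key)]
    bcls[is.na(bcls)] <- "excluded"
    rec_u <- data.frame(
      case_id = case_id, side = side, state = "unbound",
      chi_unb[, c("res_key", "res_type",
                  paste0("chi", 1:4), "n_chi", "complete")],
      class = bcls, stringsAsFactors = FALSE
    )
    rec <- rbind(rec, rec_u)
  }
  rec
}

#' Process one benchmark case into residue records
#'
#' Runs the full per-case protocol: monomer extraction, monomer and
#' in-complex SASA, SASA loss upon binding, surface/interface
#' classification, bound/unbound correspondence, and chi-angle
#' computation. Unbound residues inherit the class of their mapped
#' bound partner.
#'
#' @param case one row of a manifest (list or 1-row data.frame).
#' @param config list from [chigrid_config()].
#' @return records data.frame; one row per residue per state with
#'   `case_id`, `side`, `state`, `res_key`, `res_type`, `chi1..chi4`,
#'   `n_chi`, `complete`, `class`.
#' @export
process_case <- function(case, config = chigrid_config()) {
  case <- as.list(case)
  rch <- split_chains(case$receptor_chains)
  lch <- split_chains(case$ligand_chains)
  cplx <- read_structure(case$complex_pdb, c(rch, lch),
                         id = case$case_id)
  rbind(
    process_side(cplx, rch, case$unbound_receptor_pdb,
                 split_chains(case$unbound_receptor_chains %||% NA),
                 case$case_id, "receptor", config),
    process_side(cplx, lch, case$unbound_ligand_pdb,
                 split_chains(case$unbound_ligand_chains %||% NA),
                 case$case_id, "ligand", config)
  )
}

#' Process every case of a manifest
#'
#' Unreadable files or missing chains skip the case with a warning; the
#' pipeline continues.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param config list from [chigrid_config()].
#' @return combined records data.frame.
#' @export
process_manifest <- function(manifest, config = chigrid_config()) {
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- tryCatch(process_case(manifest[i, ], config),
                    error = function(e) {
                      warnf("case '%s' skipped: %s",
                            manifest$case_id[i], conditionMessage(e))
                      NULL
                    })
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  if (length(out) == 0L) stopf("no case processed successfully")
  do.call(rbind, out)
}

#' Per-type residue counts by class and state
#'
#' @param records records data.frame (from [process_case()] or
#'   [synthetic_benchmark()]).
#' @return data.frame with one row per chi-bearing residue type and the
#'   counts `interface_unbound`, `interface_bound`,
#'   `non_interface_unbound`, `non_interface_bound`.
#' @export
residue_counts <- function(records) {
  types <- names(CHI_CHAIN)
  cnt <- function(cls, st) {
    sel <- records$class == cls & records$state == st
    as.integer(table(factor(records$res_type[sel], levels = types)))
  }
  data.frame(
    res_type = types,
    interface_unbound = cnt("interface", "unbound"),
    interface_bound = cnt("interface", "bound"),
    non_interface_unbound = cnt("non_interface_surface", "unbound"),
    non_interface_bound = cnt("non_interface_surface", "bound"),
    stringsAsFactors = FALSE
  )
}

CATEGORY_PAIRS <- list(
  interface_bound_vs_unbound =
    list(x = c("interface", "unbound"), y = c("interface", "bound")),
  non_interface_bound_vs_unbound =
    list(x = c("non_interface_surface", "unbound"),
         y = c("non_interface_surface", "bound")),
  unbound_non_interface_vs_interface =
    list(x = c("non_interface_surface", "unbound"),
         y = c("interface", "unbound")),
  bound_non_interface_vs_interface =
    list(x = c("non_interface_surface", "bound"),
         y = c("interface", "bound"))
)

pool_matrix <- function(records, res_type, cls, state) {
  sel <- records$res_type == res_type & records$class == cls &
    records$state == state & records$complete
  nchi <- chi_count(res_type)
  as.matrix(records[sel, paste0("chi", seq_len(nchi)), drop = FALSE])
}

#' Run the four-category comparison analysis
#'
#' For every chi-bearing residue type present and every category pair
#' (interface bound vs unbound, non-interface bound vs unbound, and
#' non-interface vs interface within each state), computes the
#' offset-averaged correlation and Manhattan distance at every scanned
#' spacing, then the critical spacing at which the mean correlation
#' reaches the threshold. Pools smaller than `min_samples` are skipped
#' and reported in the `skipped` table.
#'
#' @param records records data.frame.
#' @param config list from [chigrid_config()]; `config$seed`, when set,
#'   makes the whole analysis reproducible.
#' @return list with `comparisons` (one row per type x pair x spacing),
#'   `critical` (one row per type x pair) and `skipped`.
#' @export
run_analysis <- function(records, config = chigrid_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  comparisons <- list(); skipped <- list(); critical <- list()
  types <- intersect(names(CHI_CHAIN), unique(records$res_type))
  for (rt in types) {
    for (pair in names(CATEGORY_PAIRS)) {
      p <- CATEGORY_PAIRS[[pair]]
      mx <- pool_matrix(records, rt, p$x[1], p$x[2])
      my <- pool_matrix(records, rt, p$y[1], p$y[2])
      if (nrow(mx) < config$min_samples || nrow(my) < config$min_samples) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          res_type = rt, category_pair = pair,
          n_x = nrow(mx), n_y = nrow(my), stringsAsFactors = FALSE)
        next
      }
      res <- do.call(rbind, lapply(config$spacings, function(sp)
        averaged_comparison(mx, my, rt, sp,
                            n_repeats = config$n_repeats)))
      res <- data.frame(res_type = rt, category_pair = pair,
                        res[, -1], stringsAsFactors = FALSE)
      comparisons[[length(comparisons) + 1L]] <- res
      critical[[length(critical) + 1L]] <- data.frame(
        res_type = rt, category_pair = pair,
        critical_spacing = critical_spacing(res$spacing, res$mean_r,
                                            config$r_threshold),
        stringsAsFactors = FALSE)
    }
  }
  list(
    comparisons = if (length(comparisons)) do.call(rbind, comparisons)
                  else NULL,
    critical = if (length(critical)) do.call(rbind, critical) else NULL,
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL
  )
}

#' Write an angle/class records table as TSV
#'
#' The pipeline's intermediate format: one row per residue per state,
#' floating point at 4 decimals.
#'
#' @param records records data.frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_angle_table <- function(records, file) {
  out <- records
  for (col in paste0("chi", 1:4))
    if (col %in% names(out)) out[[col]] <- round(out[[col]], 4)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read an angle/class records table
#'
#' @param file TSV path written by [write_angle_table()].
#' @return records data.frame.
#' @export
read_angle_table <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write comparison and critical-spacing tables
#'
#' @param analysis list from [run_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE) &
      !vapply(df, is.integer, TRUE)
    df[num] <- lapply(df[num], function(x) round(x, 4))
    df
  }
  if (!is.null(analysis$comparisons))
    utils::write.table(fmt(analysis$comparisons),
                       file.path(dir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(analysis$critical))
    utils::write.table(analysis$critical,
                       file.path(dir, "critical_spacing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(analysis$skipped))
    utils::write.table(analysis$skipped, file.path(dir, "skipped.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
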