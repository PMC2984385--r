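# Plain-text serialisation of maps, designs and results.
#
# All writes are atomic (temp file + rename). Formats are TSV with header
# lines, '.' decimal separator, alleles coded 0/1 and haplotype strings
# map-ordered left to right.

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("cannot write ", path)
  invisible(path)
}

write_tsv <- function(df, path) {
  atomic_write(path, function(p) {
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Write / read a genetic map file
#'
#' TSV with header `marker_id  position_cM`.
#'
#' @param map A `genetic_map`.
#' @param path File path.
#' @return `read_map()` returns a `genetic_map` (without QTL position,
#'   which is simulation truth and lives in the run manifest).
#' @export
write_map <- function(map, path) {
  write_tsv(data.frame(marker_id = map$marker_ids,
                       position_cM = map$positions), path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  if (!identical(names(df), c("marker_id", "position_cM"))) {
    stop("map file must have columns marker_id, position_cM")
  }
  genetic_map(df$position_cM, df$marker_id)
}

allele_string <- function(m) apply(m, 1L, paste, collapse = "")

parse_alleles <- function(s, n_markers, line) {
  v <- as.integer(strsplit(s, "")[[1]])
  if (length(v) != n_markers || any(is.na(v)) || any(!v %in% 0:1)) {
    stop("line ", line, ": allele string must be ", n_markers,
         " characters over {0,1}")
  }
  v
}

#' Write a simulated half-sib design to a directory
#'
#' Produces `map.tsv`, `haplotypes.tsv` (`individual_id role sire_id
#' alleles`; two `sire` rows per sire, then `progeny_pat` / `progeny_mat`
#' rows per progeny), `phenotypes.tsv`, a `truth.tsv` with the simulated
#' QTL alleles and a JSON `manifest.json` holding the true QTL position and
#' any configuration passed in.
#'
#' @param design A `halfsib_design`.
#' @param dir Output directory (created if needed).
#' @param config Optional configuration list stored in the manifest.
#' @param seed Optional seed stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_design <- function(design, dir, config = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_map(design$map, file.path(dir, "map.tsv"))
  ns <- design$n_sires; np <- design$n_progeny
  sire_ids <- paste0("S", seq_len(ns))
  prog_ids <- paste0("P", seq_len(np))
  haps <- rbind(
    data.frame(individual_id = rep(sire_ids, each = 2L), role = "sire",
               sire_id = ".",
               alleles = as.vector(rbind(allele_string(design$sire_hap1),
                                         allele_string(design$sire_hap2)))),
    data.frame(individual_id = rep(prog_ids, 2L),
               role = rep(c("progeny_pat", "progeny_mat"), each = np),
               sire_id = rep(sire_ids[design$sire], 2L),
               alleles = c(allele_string(design$pat),
                           allele_string(design$mat))))
  write_tsv(haps, file.path(dir, "haplotypes.tsv"))
  write_tsv(data.frame(individual_id = prog_ids,
                       sire_id = sire_ids[design$sire],
                       phenotype = design$y),
            file.path(dir, "phenotypes.tsv"))
  write_tsv(data.frame(
    individual_id = c(sire_ids, prog_ids),
    qtl_allele_1 = c(design$sire_qtl1, design$pat_qtl),
    qtl_allele_2 = c(design$sire_qtl2, design$mat_qtl)),
    file.path(dir, "truth.tsv"))
  write_manifest(file.path(dir, "manifest.json"),
                 config = config, seed = seed,
                 extra = list(true_qtl_cM = design$map$qtl_position,
                              generations = design$generations))
  invisible(dir)
}

#' Read a half-sib design from map, haplotype and phenotype files
#'
#' Validates the schemas described in [write_design()]: every progeny must
#' reference a known sire and carry one paternal and one maternal
#' haplotype, every sire exactly two haplotypes, and all allele strings
#' must match the map length; violations are reported with line numbers.
#'
#' @param map_path,haps_path,phen_path File paths.
#' @param generations Optional generations-since-founding annotation used
#'   by the LDL scan.
#' @return A `halfsib_design` (QTL truth fields are `NA`).
#' @export
read_design <- function(map_path, haps_path, phen_path,
                        generations = NULL) {
  map <- read_map(map_path)
  M <- map$n_markers
  hp <- utils::read.table(haps_path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!identical(names(hp), c("individual_id", "role", "sire_id", "alleles"))) {
    stop("haplotype file must have columns individual_id, role, sire_id, alleles")
  }
  bad_role <- which(!hp$role %in% c("sire", "progeny_pat", "progeny_mat"))
  if (length(bad_role)) {
    stop("line ", bad_role[1] + 1L, ": unknown role '", hp$role[bad_role[1]], "'")
  }
  al <- t(vapply(seq_len(nrow(hp)),
                 function(i) parse_alleles(hp$alleles[i], M, i + 1L),
                 integer(M)))

  si <- hp$role == "sire"
  sire_ids <- unique(hp$individual_id[si])
  if (any(table(hp$individual_id[si]) != 2L)) {
    stop("every sire must have exactly two haplotype rows")
  }
  sire_rows <- hp$individual_id[si]
  sh1 <- al[si, , drop = FALSE][match(sire_ids, sire_rows), , drop = FALSE]
  last_row <- length(sire_rows) + 1L - match(sire_ids, rev(sire_rows))
  sh2 <- al[si, , drop = FALSE][last_row, , drop = FALSE]

  pp <- hp$role == "progeny_pat"
  pm <- hp$role == "progeny_mat"
  prog_ids <- unique(hp$individual_id[pp])
  if (anyDuplicated(hp$individual_id[pp]) || anyDuplicated(hp$individual_id[pm])) {
    stop("duplicated progeny haplotype rows")
  }
  if (!setequal(prog_ids, hp$individual_id[pm])) {
    stop("every progeny needs one paternal and one maternal haplotype")
  }
  pat <- al[pp, , drop = FALSE][match(prog_ids, hp$individual_id[pp]), , drop = FALSE]
  mat <- al[pm, , drop = FALSE][match(prog_ids, hp$individual_id[pm]), , drop = FALSE]
  sire_of_prog <- hp$sire_id[pp][match(prog_ids, hp$individual_id[pp])]
  sire_idx <- match(sire_of_prog, sire_ids)
  if (anyNA(sire_idx)) {
    stop("progeny ", prog_ids[which(is.na(sire_idx))[1]],
         " references an unknown sire")
  }

  ph <- utils::read.table(phen_path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  if (!identical(names(ph), c("individual_id", "sire_id", "phenotype"))) {
    stop("phenotype file must have columns individual_id, sire_id, phenotype")
  }
  y <- ph$phenotype[match(prog_ids, ph$individual_id)]
  if (anyNA(y) || any(!is.finite(y))) stop("missing or non-finite phenotypes")

  np <- length(prog_ids)
  new_halfsib_design(map, sh1, sh2,
                     sire_qtl1 = rep(NA_integer_, length(sire_ids)),
                     sire_qtl2 = rep(NA_integer_, length(sire_ids)),
                     pat = pat, mat = mat,
                     pat_qtl = rep(NA_integer_, np),
                     mat_qtl = rep(NA_integer_, np),
                     sire = sire_idx, y = y, generations = generations)
}

#' Read phased haplotypes from a VCF file
#'
#' Optional phased-VCF input (requires the `vcfR` package): all genotypes
#' must be phased (`a|b`); the first allele of each sample is taken as
#' chromosome 1. For sires that is haplotype 1 / 2; for progeny the first
#' allele is the paternal and the second the maternal haplotype. Variants
#' are matched to the map by marker id.
#'
#' @param map_path,vcf_path,phen_path File paths; the phenotype file names
#'   the progeny and their sires (samples present in `sire_id` are sires).
#' @param generations Optional generations annotation.
#' @return A `halfsib_design`.
#' @export
read_design_vcf <- function(map_path, vcf_path, phen_path,
                            generations = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_design_vcf requires the vcfR package")
  }
  map <- read_map(map_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ids <- v@fix[, "ID"]
  ord <- match(map$marker_ids, ids)
  if (anyNA(ord)) stop("VCF is missing markers: ",
                       paste(map$marker_ids[is.na(ord)], collapse = ", "))
  gt <- vcfR::extract.gt(v)[ord, , drop = FALSE]
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("unphased genotype found; phased '|' genotypes are required")
  }
  hap <- function(sample, k) {
    as.integer(vapply(strsplit(gt[, sample], "|", fixed = TRUE),
                      `[[`, character(1), k))
  }
  ph <- utils::read.table(phen_path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  sire_ids <- unique(ph$sire_id)
  prog_ids <- ph$individual_id
  missing <- setdiff(c(sire_ids, prog_ids), colnames(gt))
  if (length(missing)) stop("VCF is missing samples: ",
                            paste(missing, collapse = ", "))
  sh1 <- unname(t(vapply(sire_ids, hap, integer(map$n_markers), k = 1L)))
  sh2 <- unname(t(vapply(sire_ids, hap, integer(map$n_markers), k = 2L)))
  pat <- unname(t(vapply(prog_ids, hap, integer(map$n_markers), k = 1L)))
  mat <- unname(t(vapply(prog_ids, hap, integer(map$n_markers), k = 2L)))
  np <- length(prog_ids)
  new_halfsib_design(map, sh1, sh2,
                     sire_qtl1 = rep(NA_integer_, length(sire_ids)),
                     sire_qtl2 = rep(NA_integer_, length(sire_ids)),
                     pat = pat, mat = mat,
                     pat_qtl = rep(NA_integer_, np),
                     mat_qtl = rep(NA_integer_, np),
                     sire = match(ph$sire_id, sire_ids),
                     y = ph$phenotype, generations = generations)
}

#' Write a scan result as TSV
#'
#' Columns `interval_index  midpoint_cM  best_haplotype  statistic` (the
#' statistic is the max-F for the association scan, the LRT for the
#' likelihood scan); an empty result writes the header only.
#'
#' @param result A `scan_result`.
#' @param path Output path.
#' @export
write_scan_result <- function(result, path) {
  df <- data.frame(interval_index = seq_along(result$midpoints),
                   midpoint_cM = result$midpoints,
                   best_haplotype = if (!is.null(result$best_hap))
                     result$best_hap else NA_character_,
                   statistic = result$stat)
  write_tsv(df, path)
}

#' Write a JSON run manifest
#'
#' @param path Output path.
#' @param config Configuration list.
#' @param seed Master seed.
#' @param extra Extra named entries.
#' @export
write_manifest <- function(path, config = NULL, seed = NULL, extra = NULL) {
  manifest <- c(list(package = "ldlmap",
                     version = as.character(utils::packageVersion("ldlmap")),
                     seed = seed, config = config),
                extra)
  atomic_write(path, function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  })
}

#' Build a scenario from a configuration list
#'
#' Accepts the fields of [scenario()] (unknown fields are an error), as
#' read from a YAML configuration file.
#'
#' @param config Named list (e.g. `yaml::read_yaml(path)`).
#' @return A [scenario()].
#' @export
scenario_from_config <- function(config) {
  known <- names(formals(scenario))
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown scenario fields: ", paste(bad, collapse = ", "))
  do.call(scenario, config)
}
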