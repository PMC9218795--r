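#' Write a simulated dataset to disk
#'
#' Emits phased VCFs (one per population plus the merged panel), a pedigree
#' CSV (`animal,sire,dam,birthdate`, founders have sire = dam = 0, birthdates
#' ordered by generation), a phenotype CSV (`animal,parity,hys,value`) and a
#' ground-truth JSON with the QTL architecture and true variance components.
#' All files round-trip losslessly through the package's readers.
#'
#' @param pop1,pop2 [phased_genotypes()] of the two populations.
#' @param pedigree Pedigree tibble from [evolve_split_populations()].
#' @param records Phenotype tibble from [simulate_phenotype_records()].
#' @param truth A `sim_truth` object (optional, written when supplied).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
emit_dataset <- function(pop1, pop2, pedigree, records, out_dir,
                         truth = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L) {
    abort(sprintf("cannot write to output directory `%s`", out_dir),
          class = "hapblup_io_error")
  }
  paths <- c(pop1 = file.path(out_dir, "pop1.vcf"),
             pop2 = file.path(out_dir, "pop2.vcf"),
             merged = file.path(out_dir, "merged.vcf"),
             pedigree = file.path(out_dir, "pedigree.csv"),
             phenotypes = file.path(out_dir, "phenotypes.csv"))
  write_phased_vcf(pop1, paths[["pop1"]])
  write_phased_vcf(pop2, paths[["pop2"]])
  write_phased_vcf(merge_populations(pop1, pop2), paths[["merged"]])
  ped_out <- pedigree |>
    arrange(.data$birthdate) |>
    select("animal", "sire", "dam", "birthdate")
  readr::write_csv(ped_out, paths[["pedigree"]])
  readr::write_csv(records, paths[["phenotypes"]])
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(out_dir, "truth.json"))
    tr <- unclass(truth)
    tr$true_breeding_values <- as.list(tr$true_breeding_values)
    tr$variance_components_true <- as.list(tr$variance_components_true)
    jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read back a truth JSON written by [emit_dataset()]
#'
#' @param path Path to `truth.json`.
#' @return A `sim_truth` object.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(qtl_snp_ids = tr$qtl_snp_ids, qtl_indices = tr$qtl_indices,
         qtl_effects = tr$qtl_effects,
         true_breeding_values = unlist(tr$true_breeding_values),
         variance_components_true = unlist(tr$variance_components_true)),
    class = "sim_truth")
}

#' One-call simulation of the reference dataset
#'
#' Convenience wrapper chaining [generate_founder_haplotypes()],
#' [evolve_split_populations()], [assign_qtl_effects()] (on the merged
#' genotyped set) and [simulate_phenotype_records()].
#'
#' @param config A [sim_config()].
#' @return A list with `config`, `pop1`, `pop2`, `merged`, `pedigree`,
#'   `records` and `truth`.
#' @export
sim_dataset <- function(config = sim_config()) {
  founders <- generate_founder_haplotypes(config)
  pops <- evolve_split_populations(founders, config)
  merged <- merge_populations(pops$pop1, pops$pop2)
  truth <- assign_qtl_effects(merged, config)
  records <- simulate_phenotype_records(merged, truth, config)
  list(config = config, pop1 = pops$pop1, pop2 = pops$pop2, merged = merged,
       pedigree = pops$pedigree, records = records, truth = truth)
}
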