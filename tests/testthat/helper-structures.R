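# Resolve deposited crystal structures by accession.  The coordinate files
# are not shipped with the package (they are external data); analyses that
# need them look under options(clampscope.structure_dir = ...) or
# inst/extdata/structures/.  Tests that require a missing accession fail
# with a pointer rather than silently skipping.

depositedStructure <- function(acc) {
  dirs <- c(getOption("clampscope.structure_dir", ""),
            system.file("extdata", "structures", package = "clampscope"))
  for (d in dirs[nzchar(dirs)]) {
    for (ext in c(".pdb", ".cif")) {
      f <- file.path(d, paste0(acc, ext))
      if (file.exists(f)) return(suppressWarnings(readStructure(f)))
    }
  }
  NULL
}

failMissingStructure <- function(acc) {
  testthat::fail(paste0(
    "deposited structure ", acc, " is not available in this environment; ",
    "download ", acc, ".pdb and place it under ",
    "options(clampscope.structure_dir = ...) to run this analysis"))
}

proteinChains <- function(model) {
  a <- atoms(model)
  unique(a$chain[a$kind == "amino_acid"])
}

nucleotideChains <- function(model) {
  a <- atoms(model)
  unique(a$chain[a$kind == "nucleotide"])
}
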