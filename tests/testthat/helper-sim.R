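# Shared small simulation configurations.  Chromosome length is shrunk so
# that SNP density per 1 Mb window resembles a 50k chip at desk scale.

test_config <- function(...) {
  defaults <- list(n_founders = 30, n_generations = 4, n_animals = 150,
                   n_chromosomes = 3, chrom_length_bp = 2e7, n_snps = 300,
                   n_genes = 20, n_traits = 2, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Six-animal pedigree with a sire-daughter mating: animal 4 (sire 1 mated
# to his daughter 3) is inbred with F = 0.25, diagonal 1.25.
inbred_pedigree <- function() {
  tibble::tibble(id = as.character(1:6),
                 sire = c(NA, NA, "1", "1", "1", "4"),
                 dam = c(NA, NA, "2", "3", "2", "5"))
}
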