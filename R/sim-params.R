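# Simulation parameter container for the synthetic genome generator.

#' Parameters for synthetic genome construction
#'
#' Defaults describe an E. coli-like context: ~50% GC i.i.d. background,
#' gene lengths 400-1500 bp, intergenic gaps 200-300 bp (wide enough that no
#' two planted promoter element sets can collide), and per-strain activity
#' multipliers for each planted promoter type across the three strains
#' (WT, dRI, none). Activator-dependent promoters fire only with wild-type
#' sigma-54 (8, 1, 1); bypass promoters retain low-level activator-independent
#' output with the Region-I-deleted form (8, 2.5, 1) and carry a non-consensus
#' -12 base; sigma-54-repressed sigma-70 promoters are derepressed when
#' sigma-54 is absent (1, 1, 8) and keep the consensus -12 C at the planted
#' sigma-54 site.
#'
#' @param gc background GC content in `[0, 1]`.
#' @param gene_length_range integer range of gene lengths (bp), min >= 200.
#' @param intergenic_range integer range of intergenic gaps (bp), min >= 170.
#' @param spacer54,spacer70 spacer lengths used when planting elements.
#' @param bypass_minus12 base written at the -12 C consensus position of
#'   bypass promoters (non-C).
#' @param repressed_classes positional classes cycled over planted repressed
#'   promoters, subset of `c("I","II","III","IV")`.
#' @param act_activator,act_bypass,act_repressed,act_constitutive per-strain
#'   activity multipliers, length-3 numeric `(WT, dRI, none)`.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(gc = 0.5,
                       gene_length_range = c(400L, 1500L),
                       intergenic_range = c(200L, 300L),
                       spacer54 = 4L,
                       spacer70 = 17L,
                       bypass_minus12 = "A",
                       repressed_classes = c("I", "II", "III", "IV"),
                       act_activator = c(WT = 8, dRI = 1, none = 1),
                       act_bypass = c(WT = 8, dRI = 2.5, none = 1),
                       act_repressed = c(WT = 1, dRI = 1, none = 8),
                       act_constitutive = c(WT = 1, dRI = 1, none = 1)) {
  stopifnot(gc > 0, gc < 1)
  gene_length_range <- as.integer(gene_length_range)
  intergenic_range <- as.integer(intergenic_range)
  stopifnot(length(gene_length_range) == 2L,
            gene_length_range[1] >= 200L,
            gene_length_range[1] <= gene_length_range[2])
  stopifnot(length(intergenic_range) == 2L,
            intergenic_range[1] >= 170L,
            intergenic_range[1] <= intergenic_range[2])
  stopifnot(spacer54 %in% 4:5, spacer70 %in% 16:18)
  bypass_minus12 <- toupper(bypass_minus12)
  stopifnot(bypass_minus12 %in% c("A", "G", "T"))
  stopifnot(all(repressed_classes %in% c("I", "II", "III", "IV")),
            length(repressed_classes) >= 1)
  for (a in list(act_activator, act_bypass, act_repressed, act_constitutive)) {
    stopifnot(length(a) == 3L, all(a > 0))
  }
  structure(
    list(
      gc = gc,
      gene_length_range = gene_length_range,
      intergenic_range = intergenic_range,
      spacer54 = as.integer(spacer54),
      spacer70 = as.integer(spacer70),
      bypass_minus12 = bypass_minus12,
      repressed_classes = as.character(repressed_classes),
      act_activator = stats::setNames(as.numeric(act_activator), STRAINS),
      act_bypass = stats::setNames(as.numeric(act_bypass), STRAINS),
      act_repressed = stats::setNames(as.numeric(act_repressed), STRAINS),
      act_constitutive = stats::setNames(as.numeric(act_constitutive), STRAINS)
    ),
    class = "sim_params"
  )
}

# Rebuild a sim_params from a plain list (e.g. parsed YAML, where named
# numeric vectors come back as named lists).
as_sim_params <- function(x) {
  if (inherits(x, "sim_params")) return(x)
  num <- function(v) unlist(v)
  sim_params(
    gc = num(x$gc),
    gene_length_range = num(x$gene_length_range),
    intergenic_range = num(x$intergenic_range),
    spacer54 = num(x$spacer54),
    spacer70 = num(x$spacer70),
    bypass_minus12 = x$bypass_minus12,
    repressed_classes = unlist(x$repressed_classes),
    act_activator = num(x$act_activator),
    act_bypass = num(x$act_bypass),
    act_repressed = num(x$act_repressed),
    act_constitutive = num(x$act_constitutive)
  )
}

activity_for_type <- function(params, type) {
  switch(type,
    sigma54_activator_dependent = params$act_activator,
    sigma54_bypass = params$act_bypass,
    sigma70_repressed_by_sigma54 = params$act_repressed,
    sigma70_constitutive = params$act_constitutive,
    params$act_constitutive
  )
}
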