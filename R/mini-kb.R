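#' Built-in miniature knowledge base
#'
#' A small, self-contained knowledge base used throughout the examples and
#' tests. It covers the classic pharmacogenomic associations: four
#' cisplatin-toxicity SNPs (rs1042522, rs316019, rs11615, rs3957357),
#' warfarin dosage variants in VKORC1, CYP2C9 and CYP4F2 (the CYP4F2 variant
#' also affecting the related coumarin anticoagulant phenprocoumon), a
#' warfarin dosage-lowering genotype at rs2292566, and a clopidogrel
#' efficacy variant in CYP2C19. Warfarin and clopidogrel rows carry the FDA
#' pharmacogenomic biomarker-label flag.
#'
#' This is a curated fixture, not a clinical resource. Gene symbols for the
#' cisplatin SNPs are placeholders (`GENE_CIS1`..`GENE_CIS4`); the rs3957357
#' genotype/direction and the gene placement of rs2292566 are fixture
#' choices, documented as such in the package vignette.
#'
#' @return A [pgx_kb] object with 11 annotation rows over 4 drugs.
#' @examples
#' kb <- mini_kb()
#' kb_lookup(kb, rsid = "rs11615")
#' @export
mini_kb <- function() {
  ann <- tibble::tribble(
    ~rsid, ~gene, ~chrom, ~pos, ~genotype, ~drug, ~aspect, ~direction,
    ~evidence, ~fda_labeled, ~description,

    "rs1042522", "GENE_CIS1", "17", 7579472L, "CC", "cisplatin",
    "toxicity", "decrease", "2A", FALSE,
    "Homozygous CC carriers show reduced cisplatin toxicity.",

    "rs316019", "GENE_CIS2", "6", 160670282L, "CC", "cisplatin",
    "toxicity", "increase", "2B", FALSE,
    "Homozygous CC carriers show increased cisplatin toxicity.",

    "rs11615", "GENE_CIS3", "19", 45923653L, "GG", "cisplatin",
    "toxicity", "decrease", "2A", FALSE,
    "Homozygous GG carriers show reduced cisplatin toxicity.",

    "rs11615", "GENE_CIS3", "19", 45923653L, "AG", "cisplatin",
    "toxicity", "increase", "2A", FALSE,
    "Heterozygous AG carriers show increased cisplatin toxicity.",

    "rs3957357", "GENE_CIS4", "6", 52668477L, "TT", "cisplatin",
    "toxicity", "decrease", "3", FALSE,
    "Fixture genotype: TT assigned reduced cisplatin toxicity.",

    "rs9923231", "VKORC1", "16", 31107689L, "AA", "warfarin",
    "dosage", "decrease", "1A", TRUE,
    "VKORC1 -1639 AA carriers require a lower warfarin dose.",

    "rs1799853", "CYP2C9", "10", 96702047L, "CT", "warfarin",
    "dosage", "decrease", "1A", TRUE,
    "CYP2C9*2 carriers require a lower warfarin dose.",

    "rs2108622", "CYP4F2", "19", 15990431L, "TT", "warfarin",
    "dosage", "increase", "1A", TRUE,
    "CYP4F2 V433M TT carriers require a higher warfarin dose.",

    "rs2292566", "CYP2C9", "10", 96405502L, "AA", "warfarin",
    "dosage", "decrease", "3", TRUE,
    "AA carriers are recommended a lower warfarin dose (fixture gene placement).",

    "rs2108622", "CYP4F2", "19", 15990431L, "TT", "phenprocoumon",
    "dosage", "increase", "2A", FALSE,
    "CYP4F2 V433M also raises phenprocoumon dose requirements.",

    "rs4244285", "CYP2C19", "10", 96541616L, "AA", "clopidogrel",
    "efficacy", "decrease", "1A", TRUE,
    "CYP2C19 poor metabolizers show diminished clopidogrel effectiveness."
  )

  drugs <- tibble::tribble(
    ~drug, ~external_id, ~categories, ~description,
    "cisplatin", "DB00515", "Antineoplastic Agents;Platinum Compounds",
    "Platinum-based chemotherapy agent forming DNA crosslinks.",
    "warfarin", "DB00682", "Anticoagulants",
    "Vitamin K antagonist used to prevent thrombosis.",
    "phenprocoumon", "DB00946", "Anticoagulants",
    "Long-acting coumarin anticoagulant.",
    "clopidogrel", "DB00758", "Platelet Aggregation Inhibitors",
    "Thienopyridine antiplatelet prodrug activated by CYP2C19."
  )

  pgx_kb(ann, drugs)
}
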