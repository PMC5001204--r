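#' Worked example: rifampin-treated human hepatocytes
#'
#' Small bundled tables from a published study of primary human hepatocytes
#' from seven donors treated with rifampin or vehicle, used as worked
#' examples and as fixtures for the table-level contracts: the enrichment
#' table of the maximally scoring functional module, its focal terms with
#' gene lists, the significant differentially expressed miRNAs, the
#' miRNA-regulated protein interaction network table, and the published
#' miRNA-function assignments.
#'
#' `hepatocyte_enrichment()` returns the module's top GO biological-process
#' and KEGG enrichment rows (`category`, `name`, `count`, `percent`,
#' `p_value`, `adjusted_p`). `hepatocyte_module_terms()` returns the seven
#' focal terms with their annotated module genes as a `genes` list column.
#' `hepatocyte_mirna_stats()` returns the 20 significant miRNAs (`mirna`,
#' `p_value`, `direction`). `hepatocyte_mirna_pin_table()` returns the
#' miRNA-gene pairs of the miRNA-regulated PIN (`gene`, `gene_log_fc`,
#' `mirna`, `p_value`, `fold_change`). `hepatocyte_mirna_functions()`
#' returns the published miRNA-function table in long form
#' (`term`, `mirna`).
#'
#' @return A tibble (see Details).
#' @name hepatocyte_example
NULL

#' @rdname hepatocyte_example
#' @export
hepatocyte_enrichment <- function() {
  go <- tibble(
    category = "GO_BP",
    name = c(
      "regulation of apoptosis", "regulation of programme cell death",
      "regulation of cell death", "negative regulation of apoptosis",
      "negative regulation of programmed cell death",
      "negative regulation of cell death", "membrane organization",
      "vesicle-mediated transport", "membrane invagination", "endocytosis",
      "response to hypoxia", "response to oxygen levels",
      "response to inorganic substance", "anti-apoptosis",
      "positive regulation of multicellular organismal process",
      "drug metabolic process", "response to metal ion", "phagocytosis",
      "response to organic substance", "regulation of tube size"),
    count = c(19L, 19L, 19L, 13L, 13L, 13L, 13L, 15L, 10L, 10L, 8L, 8L, 9L,
              9L, 9L, 4L, 7L, 5L, 14L, 5L),
    percent = c(22.6, 22.6, 22.6, 15.5, 15.5, 15.5, 15.5, 17.9, 11.9, 11.9,
                9.5, 9.5, 10.7, 10.7, 10.7, 4.8, 8.3, 6, 16.7, 6),
    p_value = c(5.1e-7, 5.9e-7, 6.2e-7, 7.9e-7, 9.1e-7, 9.4e-7, 1.7e-6,
                4.5e-6, 4.7e-6, 4.7e-6, 1.2e-5, 1.6e-5, 2.3e-5, 2.4e-5,
                7.9e-5, 9.8e-5, 9.8e-5, 1.6e-4, 2.2e-4, 2.4e-4),
    adjusted_p = c(7.3e-4, 4.2e-4, 3.0e-4, 2.8e-4, 2.6e-4, 2.2e-4, 3.5e-4,
                   8.1e-4, 7.4e-4, 7.4e-4, 1.7e-3, 2.1e-3, 2.7e-3, 2.6e-3,
                   8.0e-3, 9.2e-3, 8.7e-3, 1.4e-2, 1.8e-2, 1.8e-2)
  )
  kegg <- tibble(
    category = "KEGG",
    name = c(
      "Metabolism of xenobiotics by cytochrome P450", "Retinol metabolism",
      "Drug metabolism", "Linoleic acid metabolism", "Pathways in cancer",
      "Focal adhesion", "Porphyrin and chlorophyll metabolism",
      "Small cell lung cancer", "ECM-receptor interaction",
      "TGF-beta signaling pathway"),
    count = c(6L, 5L, 5L, 3L, 8L, 6L, 3L, 4L, 4L, 4L),
    percent = c(7.1, 6, 6, 3.6, 9.5, 7.1, 3.6, 4.8, 4.8, 4.8),
    p_value = c(2.0e-4, 1.4e-3, 2.4e-3, 2.7e-2, 2.9e-2, 3.7e-2, 3.7e-2,
                4.2e-2, 4.2e-2, 4.6e-2),
    adjusted_p = c(1.7e-2, 6.0e-2, 6.7e-2, 4.5e-1, 4.0e-1, 4.1e-1, 3.7e-1,
                   3.7e-1, 3.7e-1, 3.6e-1)
  )
  bind_rows(go, kegg)
}

#' @rdname hepatocyte_example
#' @export
hepatocyte_module_terms <- function() {
  tibble(
    name = c("Response to drug",
             "Metabolism of xenobiotics by cytochrome P450",
             "Retinol metabolism", "Drug metabolism",
             "Linoleic acid metabolism", "Pathways in cancer",
             "Focal adhesion"),
    category = c("GO_BP", rep("KEGG", 6)),
    p_value = c(3.6e-2, 2.0e-4, 1.4e-3, 2.4e-3, 2.7e-2, 2.9e-2, 3.7e-2),
    genes = list(
      c("ABCB1", "UGT1A4", "CAV1", "CAV2"),
      c("UGT1A4", "ADH6", "CYP1A1", "CYP2C19", "CYP2C9", "CYP2E1"),
      c("UGT1A4", "ADH6", "CYP1A1", "CYP2C19", "CYP2C9"),
      c("UGT1A4", "ADH6", "CYP2C19", "CYP2C9", "CYP2E1"),
      c("CYP2C19", "CYP2C9", "CYP2E1"),
      c("CEBPA", "CREBBP", "SMAD3", "TRAF2", "BIRC3", "EGLN2", "FN1", "IKBKG"),
      c("BIRC3", "CAV1", "CAV2", "FN1", "ITGA1", "THBS1")
    )
  )
}

#' @rdname hepatocyte_example
#' @export
hepatocyte_mirna_stats <- function() {
  tibble(
    mirna = c("miR-886-3p", "miR-766", "miR-92a", "miR-107", "miR-30d#",
              "miR-335", "miR-660", "miR-638", "miR-25", "miR-616",
              "miR-576-3p", "miR-218",
              "miR-186", "miR-361", "miR-95", "miR-345", "miR-320",
              "miR-202", "miR-200b#", "let-7g"),
    p_value = c(0.0002, 0.0075, 0.0169, 0.0177, 0.0195, 0.0241, 0.0297,
                0.0302, 0.0338, 0.0446, 0.0453, 0.0499,
                0.0018, 0.0111, 0.0219, 0.0239, 0.0376, 0.0396, 0.0426,
                0.0435),
    direction = c(rep("up", 12), rep("down", 8))
  )
}

#' @rdname hepatocyte_example
#' @export
hepatocyte_mirna_pin_table <- function() {
  tibble(
    gene = c("CYP2E1",
             "CAV1", "CAV1", "CAV1", "CAV1",
             "CAV2", "CAV2",
             "CEBPA",
             "CREBBP", "CREBBP", "CREBBP",
             "EGLN2", "EGLN2",
             "ITGA1", "ITGA1", "ITGA1", "ITGA1",
             "THBS1", "THBS1", "THBS1", "THBS1"),
    gene_log_fc = c(-1.4341,
                    -0.8518, -0.8518, -0.8518, -0.8518,
                    -0.5386, -0.5386,
                    0.5812,
                    0.3821, 0.3821, 0.3821,
                    0.4574, 0.4574,
                    -0.3754, -0.3754, -0.3754, -0.3754,
                    -0.3951, -0.3951, -0.3951, -0.3951),
    mirna = c("miR-335",
              "miR-34b", "miR-886-3p", "miR-218", "miR-576-3p",
              "miR-200c", "miR-576-3p",
              "miR-186",
              "miR-186", "miR-95", "miR-769",
              "miR-202", "let-7g",
              "miR-616", "miR-660", "miR-576-3p", "miR-335",
              "miR-886-3p", "miR-335", "miR-616", "miR-92a"),
    p_value = c(0.0242,
                0.1753, 0.0001, 0.0499, 0.0453,
                0.0913, 0.0453,
                0.0017,
                0.0017, 0.0216, 0.1249,
                0.0396, 0.0435,
                0.0446, 0.0297, 0.0453, 0.0242,
                0.0001, 0.0242, 0.0446, 0.0169),
    fold_change = c(1.3300,
                    185.3764, 1.5645, 1.9012, 2.1916,
                    4.8313, 2.1916,
                    0.8356,
                    0.8356, 0.6320, 0.8388,
                    0.5988, 0.8402,
                    1.3337, 1.2642, 2.1916, 1.3300,
                    1.5645, 1.3300, 1.3337, 1.1319)
  )
}

#' @rdname hepatocyte_example
#' @export
hepatocyte_mirna_functions <- function() {
  tibble(
    term = c(rep("Response to drug", 5),
             "Metabolism of xenobiotics by cytochrome P450",
             "Drug metabolism", "Linoleic acid metabolism",
             rep("Pathways in cancer", 3),
             rep("Focal adhesion", 9)),
    mirna = c("miR-34b", "miR-886-3p", "miR-218", "miR-576-3p", "miR-200c",
              "miR-335",
              "miR-335", "miR-335",
              "miR-186", "miR-95", "miR-769",
              "miR-34b", "miR-886-3p", "miR-218", "miR-576-3p", "miR-200c",
              "miR-616", "miR-660", "miR-335", "miR-92a")
  )
}
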