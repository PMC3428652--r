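test_that("priority classes follow the published name ordering", {
  expect_equal(priority_class(fx, "Hormone"), "specific_functional")
  expect_equal(priority_class(fx, "Steroid"), "structural")
  expect_equal(priority_class(fx, "Pharmacologic Substance"), "general_functional")
  expect_equal(priority_class(fx, c("Antibiotic", "Enzyme", "Vitamin",
                                    "Receptor", "Biomedical or Dental Material",
                                    "Indicator, Reagent, or Diagnostic Aid")),
               rep("specific_functional", 6))
  expect_equal(priority_class(fx, c("Immunologic Factor",
                                    "Biologically Active Substance",
                                    "Hazardous or Poisonous Substance")),
               rep("general_functional", 3))
  net2 <- semantic_network(
    rbind(fx$types, data.frame(tui = "T073", name = "Manufactured Object",
                               tree_number = "A1.3.1", definition = "")),
    fx$edges)
  expect_error(priority_class(net2, "T073"), class = "cssn_domain_error")
})

test_that("rendered names reproduce the published intersection names", {
  rn <- function(...) render_name(c(...), fx)
  # listing and hierarchy examples
  expect_equal(rn("Amino Acid, Peptide, or Protein", "Immunologic Factor"),
               "Immunologic Amino Acid, Peptide, or Protein")
  expect_equal(rn("Amino Acid, Peptide, or Protein", "Pharmacologic Substance"),
               "Pharmacologic Amino Acid, Peptide, or Protein")
  expect_equal(rn("Amino Acid, Peptide, or Protein", "Pharmacologic Substance",
                  "Immunologic Factor"),
               "Pharmacologic Immunologic Amino Acid, Peptide, or Protein")
  expect_equal(rn("Pharmacologic Substance", "Immunologic Factor"),
               "Pharmacologic Immunologic Factor")
  expect_equal(rn("Organic Chemical", "Pharmacologic Substance"),
               "Pharmacologic Organic Chemical")
  expect_equal(rn("Organic Chemical", "Pharmacologic Substance",
                  "Hazardous or Poisonous Substance"),
               "Pharmacologic Hazardous or Poisonous Organic Chemical")
  expect_equal(rn("Pharmacologic Substance", "Steroid", "Hormone"),
               "Pharmacologic Steroid Hormone")
  expect_equal(rn("Pharmacologic Substance", "Steroid"), "Pharmacologic Steroid")
  # a pure type keeps its semantic-type name unchanged
  expect_equal(rn("Lipid"), "Lipid")
  expect_equal(rn("Hazardous or Poisonous Substance"),
               "Hazardous or Poisonous Substance")
})

test_that("rendered names reproduce the published categorization-sample names", {
  rn <- function(...) render_name(c(...), fx)
  expect_equal(rn("Biologically Active Substance",
                  "Amino Acid, Peptide, or Protein"),
               "Biologically Active Amino Acid, Peptide, or Protein")
  expect_equal(rn("Amino Acid, Peptide, or Protein", "Enzyme"),
               "Amino Acid, Peptide, or Protein Enzyme")
  expect_equal(rn("Neuroreactive Substance or Biogenic Amine",
                  "Amino Acid, Peptide, or Protein"),
               "Neuroreactive or Biogenic Amine Amino Acid, Peptide, or Protein")
  expect_equal(rn("Inorganic Chemical", "Biomedical or Dental Material"),
               "Inorganic Biomedical or Dental Material")
  expect_equal(rn("Inorganic Chemical", "Pharmacologic Substance"),
               "Pharmacologic Inorganic Chemical")
  expect_equal(rn("Inorganic Chemical", "Hazardous or Poisonous Substance"),
               "Hazardous or Poisonous Inorganic Chemical")
  expect_equal(rn("Organic Chemical", "Antibiotic"), "Organic Antibiotic")
  expect_equal(rn("Organic Chemical", "Biologically Active Substance"),
               "Biologically Active Organic Chemical")
  expect_equal(rn("Organic Chemical", "Hazardous or Poisonous Substance"),
               "Hazardous or Poisonous Organic Chemical")
  expect_equal(rn("Organic Chemical", "Indicator, Reagent, or Diagnostic Aid"),
               "Organic Indicator, Reagent, or Diagnostic Aid")
  expect_equal(rn("Organic Chemical", "Pharmacologic Substance", "Hormone"),
               "Pharmacologic Organic Hormone")
  expect_equal(rn("Organic Chemical", "Vitamin"), "Organic Vitamin")
  expect_equal(rn("Organophosphorus Compound",
                  "Indicator, Reagent, or Diagnostic Aid"),
               "Organophosphorus Indicator, Reagent, or Diagnostic Aid")
})

test_that("structural ties are ordered by tree number, not alphabetically", {
  expect_equal(render_name(c("Carbohydrate", "Lipid"), fx), "Carbohydrate Lipid")
  # alphabetical order would put Carbohydrate before the nucleic acids
  expect_equal(render_name(c("Nucleic Acid, Nucleoside, or Nucleotide",
                             "Carbohydrate"), fx),
               "Nucleic Acid, Nucleoside, or Nucleotide Carbohydrate")
  expect_equal(render_name(c("Nucleic Acid, Nucleoside, or Nucleotide",
                             "Amino Acid, Peptide, or Protein"), fx),
               "Nucleic Acid, Nucleoside, or Nucleotide Amino Acid, Peptide, or Protein")
})

test_that("the rightmost name component always names a member of the signature", {
  rules <- name_rules()
  withr::with_seed(17, {
    for (rep in 1:30) {
      members <- sample(setdiff(CHEM, st_tui(fx, "Chemical")), sample(2:4, 1))
      nm <- render_name(members, fx)
      heads <- rules$head_form[match(members, rules$tui)]
      expect_true(any(vapply(heads, function(h) endsWith(nm, h), logical(1L))),
                  info = nm)
    }
  })
})

test_that("listing placement follows the rightmost-components parent", {
  avail <- c(key_of("Amino Acid, Peptide, or Protein", "Immunologic Factor"),
             key_of("Amino Acid, Peptide, or Protein", "Pharmacologic Substance"),
             key_of("Pharmacologic Substance", "Immunologic Factor"))
  # a 2-IST is placed under its head pure type
  expect_equal(placement_parent(c("Amino Acid, Peptide, or Protein",
                                  "Pharmacologic Substance"), avail, fx),
               st_tui(fx, "Amino Acid, Peptide, or Protein"))
  # the 3-IST goes under the 2-IST carrying its rightmost components
  expect_equal(placement_parent(c("Amino Acid, Peptide, or Protein",
                                  "Pharmacologic Substance",
                                  "Immunologic Factor"), avail, fx),
               key_of("Amino Acid, Peptide, or Protein", "Immunologic Factor"))
  # Pharmacologic Steroid Hormone sits under the pure type Hormone
  expect_equal(placement_parent(c("Pharmacologic Substance", "Steroid", "Hormone"),
                                key_of("Pharmacologic Substance", "Steroid"), fx),
               st_tui(fx, "Hormone"))
  # a pure type is placed under its semantic-network parent
  expect_equal(placement_parent("Steroid", character(0), fx), st_tui(fx, "Lipid"))
})
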