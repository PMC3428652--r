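{
  "release": ["2009AA"],
  "root": ["Chemical"],
  "types": {
    "tui": ["T103", "T104", "T109", "T114", "T115", "T116", "T118", "T119", "T110", "T111", "T196", "T197", "T120", "T121", "T195", "T122", "T123", "T124", "T125", "T126", "T127", "T129", "T192", "T130", "T131"],
    "name": ["Chemical", "Chemical Viewed Structurally", "Organic Chemical", "Nucleic Acid, Nucleoside, or Nucleotide", "Organophosphorus Compound", "Amino Acid, Peptide, or Protein", "Carbohydrate", "Lipid", "Steroid", "Eicosanoid", "Element, Ion, or Isotope", "Inorganic Chemical", "Chemical Viewed Functionally", "Pharmacologic Substance", "Antibiotic", "Biomedical or Dental Material", "Biologically Active Substance", "Neuroreactive Substance or Biogenic Amine", "Hormone", "Enzyme", "Vitamin", "Immunologic Factor", "Receptor", "Indicator, Reagent, or Diagnostic Aid", "Hazardous or Poisonous Substance"],
    "tree_number": ["A1.4.1", "A1.4.1.2", "A1.4.1.2.1", "A1.4.1.2.1.5", "A1.4.1.2.1.6", "A1.4.1.2.1.7", "A1.4.1.2.1.8", "A1.4.1.2.1.9", "A1.4.1.2.1.9.1", "A1.4.1.2.1.9.2", "A1.4.1.2.2", "A1.4.1.2.3", "A1.4.1.1", "A1.4.1.1.1", "A1.4.1.1.1.1", "A1.4.1.1.2", "A1.4.1.1.3", "A1.4.1.1.3.1", "A1.4.1.1.3.2", "A1.4.1.1.3.3", "A1.4.1.1.3.4", "A1.4.1.1.3.5", "A1.4.1.1.3.6", "A1.4.1.1.4", "A1.4.1.1.5"],
    "definition": ["A compound or substance of definite molecular composition, viewed functionally and structurally.", "A chemical viewed according to its structural characteristics.", "The general class of carbon-containing compounds.", "A complex compound of high molecular weight occurring in living cells, or its constituent bases and sugars.", "An organic compound containing phosphorus as a constituent.", "Amino acids and chains of amino acids connected by peptide linkages.", "A generic term that includes monosaccharides, oligosaccharides, and polysaccharides as well as substances derived from them.", "An inclusive group of fat or fat-derived substances that are soluble in nonpolar solvents and insoluble in water.", "One of a group of polycyclic, 17-carbon-atom, fused-ring compounds occurring both in natural and synthetic forms.", "An oxygenated metabolite from polyunsaturated 20-carbon fatty acids, including the prostaglandins and related compounds.", "One of the basic units of matter, a charged form thereof, or a form differing in atomic mass.", "Chemical elements and their compounds not classed as organic.", "A chemical viewed according to its use, effect, or role.", "A substance used in the prevention, diagnosis, treatment, or mitigation of disease.", "A pharmacologically active compound produced by or derived from microorganisms that inhibits or destroys other microorganisms.", "A substance used in biomedicine or dentistry predominantly for its physical rather than chemical properties.", "A generally endogenous substance produced by or required by an organism that exerts a biological effect.", "An endogenous substance whose activities affect or play an important role in the functioning of the nervous system.", "A chemical, usually secreted by an endocrine gland, that is conveyed to another part of the body to effect physiological activity.", "A complex chemical, usually a protein, that catalyzes chemical reactions.", "A substance required in small amounts in the diet for normal growth and metabolic processes.", "A biologically active substance whose activities affect or play a role in the functioning of the immune system.", "A specific structure or site on the cell surface or within its cytoplasm that recognizes and binds with other specific molecules.", "A substance primarily of interest for its use in laboratory or diagnostic tests and procedures.", "A substance of concern because of its potentially hazardous or toxic nature."]
  },
  "edges": {
    "child": ["T120", "T104", "T121", "T195", "T122", "T123", "T124", "T125", "T126", "T127", "T129", "T192", "T130", "T131", "T109", "T114", "T115", "T116", "T118", "T119", "T110", "T111", "T196", "T197"],
    "parent": ["T103", "T103", "T120", "T121", "T120", "T120", "T123", "T123", "T123", "T123", "T123", "T123", "T120", "T120", "T104", "T109", "T109", "T109", "T109", "T109", "T119", "T119", "T104", "T104"]
  }
}
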