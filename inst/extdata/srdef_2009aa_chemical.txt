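STY|T103|Chemical|A1.4.1|A compound or substance of definite molecular composition, viewed functionally and structurally.||||chem|NULL|
STY|T104|Chemical Viewed Structurally|A1.4.1.2|A chemical viewed according to its structural characteristics.||||chvs|NULL|
STY|T109|Organic Chemical|A1.4.1.2.1|The general class of carbon-containing compounds.||||orch|NULL|
STY|T114|Nucleic Acid, Nucleoside, or Nucleotide|A1.4.1.2.1.5|A complex compound of high molecular weight occurring in living cells, or its constituent bases and sugars.||||nnon|NULL|
STY|T115|Organophosphorus Compound|A1.4.1.2.1.6|An organic compound containing phosphorus as a constituent.||||opco|NULL|
STY|T116|Amino Acid, Peptide, or Protein|A1.4.1.2.1.7|Amino acids and chains of amino acids connected by peptide linkages.||||aapp|NULL|
STY|T118|Carbohydrate|A1.4.1.2.1.8|A generic term that includes monosaccharides, oligosaccharides, and polysaccharides as well as substances derived from them.||||carb|NULL|
STY|T119|Lipid|A1.4.1.2.1.9|An inclusive group of fat or fat-derived substances that are soluble in nonpolar solvents and insoluble in water.||||lipd|NULL|
STY|T110|Steroid|A1.4.1.2.1.9.1|One of a group of polycyclic, 17-carbon-atom, fused-ring compounds occurring both in natural and synthetic forms.||||strd|NULL|
STY|T111|Eicosanoid|A1.4.1.2.1.9.2|An oxygenated metabolite from polyunsaturated 20-carbon fatty acids, including the prostaglandins and related compounds.||||eico|NULL|
STY|T196|Element, Ion, or Isotope|A1.4.1.2.2|One of the basic units of matter, a charged form thereof, or a form differing in atomic mass.||||elii|NULL|
STY|T197|Inorganic Chemical|A1.4.1.2.3|Chemical elements and their compounds not classed as organic.||||inch|NULL|
STY|T120|Chemical Viewed Functionally|A1.4.1.1|A chemical viewed according to its use, effect, or role.||||chvf|NULL|
STY|T121|Pharmacologic Substance|A1.4.1.1.1|A substance used in the prevention, diagnosis, treatment, or mitigation of disease.||||phsu|NULL|
STY|T195|Antibiotic|A1.4.1.1.1.1|A pharmacologically active compound produced by or derived from microorganisms that inhibits or destroys other microorganisms.||||antb|NULL|
STY|T122|Biomedical or Dental Material|A1.4.1.1.2|A substance used in biomedicine or dentistry predominantly for its physical rather than chemical properties.||||bodm|NULL|
STY|T123|Biologically Active Substance|A1.4.1.1.3|A generally endogenous substance produced by or required by an organism that exerts a biological effect.||||bacs|NULL|
STY|T124|Neuroreactive Substance or Biogenic Amine|A1.4.1.1.3.1|An endogenous substance whose activities affect or play an important role in the functioning of the nervous system.||||nsba|NULL|
STY|T125|Hormone|A1.4.1.1.3.2|A chemical, usually secreted by an endocrine gland, that is conveyed to another part of the body to effect physiological activity.||||horm|NULL|
STY|T126|Enzyme|A1.4.1.1.3.3|A complex chemical, usually a protein, that catalyzes chemical reactions.||||enzy|NULL|
STY|T127|Vitamin|A1.4.1.1.3.4|A substance required in small amounts in the diet for normal growth and metabolic processes.||||vita|NULL|
STY|T129|Immunologic Factor|A1.4.1.1.3.5|A biologically active substance whose activities affect or play a role in the functioning of the immune system.||||imft|NULL|
STY|T192|Receptor|A1.4.1.1.3.6|A specific structure or site on the cell surface or within its cytoplasm that recognizes and binds with other specific molecules.||||rcpt|NULL|
STY|T130|Indicator, Reagent, or Diagnostic Aid|A1.4.1.1.4|A substance primarily of interest for its use in laboratory or diagnostic tests and procedures.||||irda|NULL|
STY|T131|Hazardous or Poisonous Substance|A1.4.1.1.5|A substance of concern because of its potentially hazardous or toxic nature.||||hops|NULL|
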