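# Potentially-actionable-target (PAT) knowledge base: 19 PAT genes plus
# MSI-H, each entry one (target, alteration_class) pair with its OncoKB
# level and ESCAT tier. SYNTHETIC / NON-CANONICAL reconstruction: the
# study's supplementary per-gene tier table is not public; genes named in
# the main text (MET, ERBB2, CDK4, EGFR, FGFR2/3, NTRK1/2/3, IDH1,
# BRCA1/2, MSI-H) are kept and the list is completed with widely used
# biliary/pan-cancer targets. Tiers are package defaults, not authoritative
# OncoKB/ESCAT assignments: reconcile against the current databases before
# clinical use. A PAT is any entry at OncoKB <= level-3A or ESCAT <= II-B;
# the final CDKN2A entry is deliberately off-PAT. `printed_label` keeps a
# source's verbatim tier wording where it differs from the normalized enum.
- target: MET
  alteration_class: amplification
  oncokb_level: L3A
  escat_tier: IIB
  drug_hint: crizotinib
- target: ERBB2
  alteration_class: amplification
  oncokb_level: L2
  escat_tier: IIB
  printed_label: OncoKB level-2B
  drug_hint: trastuzumab + pertuzumab
- target: CDK4
  alteration_class: amplification
  oncokb_level: L4
  escat_tier: IIB
  drug_hint: palbociclib
- target: EGFR
  alteration_class: activating_mutation
  oncokb_level: L3A
  escat_tier: IIIA
  drug_hint: afatinib (requires EGFR IHC 2+/3+)
- target: FGFR2
  alteration_class: fusion
  oncokb_level: L1
  escat_tier: IB
  drug_hint: pemigatinib
- target: FGFR3
  alteration_class: fusion
  oncokb_level: L2
  escat_tier: IIB
  drug_hint: erdafitinib
- target: NTRK1
  alteration_class: fusion
  oncokb_level: L1
  escat_tier: IC
  drug_hint: larotrectinib
- target: NTRK2
  alteration_class: fusion
  oncokb_level: L1
  escat_tier: IC
  drug_hint: larotrectinib
- target: NTRK3
  alteration_class: fusion
  oncokb_level: L1
  escat_tier: IC
  drug_hint: larotrectinib
- target: IDH1
  alteration_class: activating_mutation
  oncokb_level: L1
  escat_tier: IB
  drug_hint: ivosidenib
- target: BRCA1
  alteration_class: truncating_mutation
  oncokb_level: L3A
  escat_tier: IIA
  drug_hint: olaparib
- target: BRCA2
  alteration_class: truncating_mutation
  oncokb_level: L3A
  escat_tier: IIA
  drug_hint: olaparib
- target: BRAF
  alteration_class: activating_mutation
  oncokb_level: L2
  escat_tier: IIB
  drug_hint: dabrafenib + trametinib
- target: PIK3CA
  alteration_class: activating_mutation
  oncokb_level: L3A
  escat_tier: IIIA
  drug_hint: alpelisib
- target: ALK
  alteration_class: fusion
  oncokb_level: L3A
  escat_tier: IIB
  drug_hint: alectinib
- target: RET
  alteration_class: fusion
  oncokb_level: L2
  escat_tier: IC
  drug_hint: selpercatinib
- target: ROS1
  alteration_class: fusion
  oncokb_level: L3A
  escat_tier: IIB
  drug_hint: crizotinib
- target: KIT
  alteration_class: activating_mutation
  oncokb_level: L3A
  escat_tier: IIB
  drug_hint: imatinib
- target: TSC1
  alteration_class: truncating_mutation
  oncokb_level: L3A
  escat_tier: IIIA
  drug_hint: everolimus
- target: MSI-H
  alteration_class: msi_high
  oncokb_level: none
  escat_tier: IC
  drug_hint: pembrolizumab
- target: CDKN2A
  alteration_class: deletion
  oncokb_level: L4
  escat_tier: IIIB
  drug_hint: palbociclib (investigational; off-PAT)
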