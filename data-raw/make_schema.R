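# Builds the bundled breast-synoptic ontology schema CSV.
# Run from the repo root:  Rscript data-raw/make_schema.R
# Produces inst/extdata/schema/breast_synoptic_schema.csv with exactly
# 8 sections, 86 subsections, 229 fields.

rows <- list()
add <- function(section, subsection, field_id, label, kind,
                options = "", template = "", synonyms = "", types = "all") {
  rows[[length(rows) + 1L]] <<- data.frame(
    section = section, subsection = subsection, field_id = field_id,
    label = label, value_kind = kind, options = options,
    numeric_template = template, synonyms = synonyms,
    report_types = types, stringsAsFactors = FALSE)
}
opt <- function(...) paste(c(...), collapse = "|")

# common option sets
YN      <- opt("Not identified", "Present")
YN3     <- opt("Not identified", "Present", "Cannot be determined")
SCORE3  <- opt("Score 1", "Score 2", "Score 3")
MARG_INV  <- opt("Cannot be assessed", "Uninvolved by invasive carcinoma",
                 "Involved by invasive carcinoma")
MARG_DCIS <- opt("Cannot be assessed", "Uninvolved by DCIS", "Involved by DCIS")
ALLT   <- "dcis|invasive_biopsy|invasive_resection|phyllodes_biopsy|phyllodes_resection"
INV    <- "invasive_biopsy|invasive_resection"
RESECT <- "dcis|invasive_resection|phyllodes_resection"
DCISON <- "dcis"
PHYLL  <- "phyllodes_biopsy|phyllodes_resection"

num <- function(section, subsection, field_id, label, template, types = "all")
  add(section, subsection, field_id, label, "numeric_template",
      options = template, template = template, types = types)

## -------- section 1: specimen (10 subsections) --------
S <- "specimen"
add(S, "Procedure", "procedure", "Procedure", "categorical",
    opt("Core needle biopsy", "Incisional biopsy",
        "Excision without wire-guided localization",
        "Excision with wire-guided localization",
        "Partial mastectomy", "Total mastectomy", "Other (specify)"),
    synonyms = "lumpectomy=>Partial mastectomy|simple mastectomy=>Total mastectomy")
add(S, "Specimen Laterality", "specimen_laterality", "Specimen Laterality",
    "categorical", opt("Right", "Left", "Not specified"))
add(S, "Specimen Site", "specimen_site", "Specimen Site", "categorical",
    opt("Upper outer quadrant", "Upper inner quadrant", "Lower outer quadrant",
        "Lower inner quadrant", "Central", "Nipple", "Not specified"))
num(S, "Specimen Size", "specimen_size_greatest",
    "Specimen Size (Greatest Dimension)", "Greatest dimension: — mm")
add(S, "Specimen Integrity", "specimen_integrity", "Specimen Integrity",
    "categorical", opt("Intact", "Fragmented"))
num(S, "Specimen Weight", "specimen_weight", "Specimen Weight",
    "Specimen weight: — g", types = RESECT)
add(S, "Lymph Node Sampling", "lymph_node_sampling", "Lymph Node Sampling",
    "categorical",
    opt("No lymph nodes submitted", "Sentinel lymph node biopsy",
        "Axillary dissection", "Other (specify)"), types = RESECT)
add(S, "Fixative Type", "fixative_type", "Fixative Type", "categorical",
    opt("Neutral buffered formalin", "Other (specify)"))
num(S, "Cold Ischemia Time", "cold_ischemia_time", "Cold Ischemia Time",
    "Cold ischemia time: — min")
num(S, "Fixation Duration", "fixation_duration", "Fixation Duration",
    "Fixation duration: — h")

## -------- section 2: tumor (22 subsections) --------
S <- "tumor"
add(S, "Tumor Site", "tumor_site", "Tumor Site", "categorical",
    opt("Upper outer quadrant", "Upper inner quadrant", "Lower outer quadrant",
        "Lower inner quadrant", "Central", "Not specified"))
add(S, "Tumor Site", "tumor_position", "Tumor Site (Clock Position)",
    "categorical",
    opt("1 o'clock", "2 o'clock", "3 o'clock", "4 o'clock", "5 o'clock",
        "6 o'clock", "7 o'clock", "8 o'clock", "9 o'clock", "10 o'clock",
        "11 o'clock", "12 o'clock"))
num(S, "Tumor Site", "tumor_position_int", "Tumor Site (Note B)",
    "Distance from nipple: — cm")
add(S, "Histologic Type", "histologic_type", "Histologic Type", "categorical",
    opt("Invasive ductal carcinoma", "Invasive lobular carcinoma",
        "Invasive carcinoma with mixed features", "Mucinous carcinoma",
        "Tubular carcinoma", "Ductal carcinoma in situ",
        "Phyllodes tumor", "Other histologic type (specify)"),
    synonyms = paste0("IDC=>Invasive ductal carcinoma|",
                      "infiltrating ductal carcinoma=>Invasive ductal carcinoma|",
                      "ILC=>Invasive lobular carcinoma"))
add(S, "Histologic Grade", "glandular_differentiation",
    "Glandular Differentiation", "categorical", SCORE3, types = INV)
add(S, "Histologic Grade", "nuclear_pleomorphism", "Nuclear Pleomorphism",
    "categorical", SCORE3, types = INV)
add(S, "Histologic Grade", "mitotic_rate", "Mitotic Rate", "categorical",
    SCORE3, types = INV)
add(S, "Histologic Grade", "overall_grade", "Overall Grade", "categorical",
    opt("Grade 1", "Grade 2", "Grade 3", "Cannot be assessed"), types = INV)
num(S, "Tumor Size", "tumor_size_greatest", "Tumor Size (Greatest Dimension)",
    "Greatest dimension of tumor: — mm")
add(S, "Tumor Size", "tumor_size_method", "Tumor Size Method", "categorical",
    opt("Gross measurement", "Microscopic measurement", "Imaging measurement"))
add(S, "Tumor Focality", "tumor_focality", "Tumor Focality", "categorical",
    opt("Single focus", "Multiple foci", "Cannot be determined"))
add(S, "DCIS Presence", "dcis_present", "Ductal Carcinoma In Situ",
    "categorical", opt("Not identified", "Present", "Cannot be determined"))
num(S, "DCIS Presence", "dcis_extent", "Extent of DCIS",
    "Estimated extent: — mm", types = "dcis|invasive_resection")
add(S, "DCIS Architectural Patterns", "dcis_patterns",
    "DCIS Architectural Patterns", "categorical",
    opt("Comedo", "Cribriform", "Micropapillary", "Papillary", "Solid"),
    types = "dcis|invasive_resection")
add(S, "DCIS Nuclear Grade", "dcis_nuclear_grade", "DCIS Nuclear Grade",
    "categorical", opt("Grade I (low)", "Grade II (intermediate)",
                       "Grade III (high)"), types = "dcis|invasive_resection")
add(S, "DCIS Necrosis", "dcis_necrosis", "DCIS Necrosis", "categorical",
    opt("Not identified", "Present, focal", "Present, central"),
    types = "dcis|invasive_resection")
add(S, "Lobular Carcinoma In Situ", "lcis_present",
    "Lobular Carcinoma In Situ", "categorical", YN)
add(S, "Lymphovascular Invasion", "lymphovascular_invasion",
    "Lymphovascular Invasion", "categorical", YN3, types = INV)
add(S, "Dermal Lymphovascular Invasion", "dermal_lvi",
    "Dermal Lymphovascular Invasion", "categorical", YN3, types = INV)
add(S, "Perineural Invasion", "perineural_invasion", "Perineural Invasion",
    "categorical", YN, types = INV)
add(S, "Skin Involvement", "skin_involvement", "Skin Involvement",
    "categorical",
    opt("Not identified", "Invades dermis", "Invades epidermis with ulceration"),
    types = RESECT)
add(S, "Nipple Involvement", "nipple_involvement", "Nipple Involvement",
    "categorical", YN, types = RESECT)
add(S, "Skeletal Muscle Involvement", "skeletal_muscle",
    "Skeletal Muscle Involvement", "categorical", YN, types = RESECT)
add(S, "Treatment Effect", "treatment_effect_tumor",
    "Treatment Effect in Breast", "categorical",
    opt("No known presurgical therapy", "No definite response",
        "Probable or definite response", "Complete response"), types = INV)
num(S, "Tumor Extent", "tumor_extent_span", "Span of Tumor Bed",
    "Span of tumor bed: — mm", types = INV)
add(S, "Microcalcifications", "microcalcifications", "Microcalcifications",
    "categorical", opt("Not identified", "Present in DCIS",
                       "Present in invasive carcinoma", "Present in benign tissue"))
add(S, "Estrogen Receptor", "er_status", "Estrogen Receptor Status",
    "categorical", opt("Positive", "Negative", "Cannot be determined"),
    synonyms = "ER positive=>Positive|ER negative=>Negative")
num(S, "Estrogen Receptor", "er_percent", "Estrogen Receptor Percent Staining",
    "Positive cells: — %")
add(S, "Progesterone Receptor", "pr_status", "Progesterone Receptor Status",
    "categorical", opt("Positive", "Negative", "Cannot be determined"))
num(S, "Progesterone Receptor", "pr_percent",
    "Progesterone Receptor Percent Staining", "PR positive cells: — %")
add(S, "HER2 Status", "her2_ihc", "HER2 by Immunohistochemistry",
    "categorical", opt("Negative (Score 0)", "Negative (Score 1+)",
                       "Equivocal (Score 2+)", "Positive (Score 3+)"))
add(S, "Phyllodes Classification", "phyllodes_class",
    "Phyllodes Tumor Classification", "categorical",
    opt("Benign", "Borderline", "Malignant"), types = PHYLL)
num(S, "Phyllodes Classification", "phyllodes_mitoses", "Mitotic Count",
    "Mitoses per 10 HPF: —", types = PHYLL)
add(S, "Phyllodes Classification", "stromal_overgrowth", "Stromal Overgrowth",
    "categorical", opt("Absent", "Present"), types = PHYLL)

## -------- section 3: margins (12 subsections) --------
S <- "margins"
dirs <- c(anterior = "Anterior", posterior = "Posterior", superior = "Superior",
          inferior = "Inferior", medial = "Medial", lateral = "Lateral",
          deep = "Deep")
for (k in names(dirs)) {
  d <- dirs[[k]]
  sub <- paste(d, "Margin")
  add(S, sub, paste0("margin_", k, "_inv"),
      paste(d, "Margin Involvement by Invasive Carcinoma"), "categorical",
      MARG_INV, types = RESECT)
  num(S, sub, paste0("margin_", k, "_inv_exact"),
      paste("Distance from Invasive Carcinoma to", d, "Margin"),
      "Exact distance: — mm", types = RESECT)
  add(S, sub, paste0("margin_", k, "_dcis"),
      paste(d, "Margin Involvement by DCIS"), "categorical",
      MARG_DCIS, types = "dcis|invasive_resection")
  id <- if (k == "anterior") "dcis_margin_exact" else
    paste0("margin_", k, "_dcis_exact")
  num(S, sub, id, paste("Distance from DCIS to", d, "Margin"),
      "Exact distance: — mm", types = "dcis|invasive_resection")
}
add(S, "Overall Margin Status", "margin_overall", "Overall Margin Status",
    "categorical", opt("Cannot be assessed", "All margins uninvolved",
                       "Margin(s) involved (specify)"), types = RESECT)
add(S, "Closest Margin", "closest_margin", "Closest Uninvolved Margin",
    "categorical", opt("Anterior", "Posterior", "Superior", "Inferior",
                       "Medial", "Lateral", "Deep"), types = RESECT)
num(S, "Closest Margin", "closest_margin_distance",
    "Distance to Closest Margin", "Closest distance: — mm", types = RESECT)
add(S, "Skin Margin", "skin_margin", "Skin Margin", "categorical",
    opt("Cannot be assessed", "Uninvolved", "Involved"), types = RESECT)
add(S, "Re-excision Margin Status", "reexcision_margin",
    "Re-excision Margin Status", "categorical",
    opt("Not applicable", "No residual carcinoma", "Residual carcinoma present"),
    types = RESECT)

## -------- section 4: regional lymph nodes (14 subsections) --------
S <- "regional lymph nodes"
num(S, "Number of Lymph Nodes Examined", "ln_examined",
    "Number of Lymph Nodes Examined", "Number examined: —", types = RESECT)
num(S, "Number of Sentinel Nodes Examined", "ln_sentinel_examined",
    "Number of Sentinel Nodes Examined", "Sentinel nodes examined: —",
    types = RESECT)
num(S, "Number of Nodes with Macrometastases", "ln_macro",
    "Number of Nodes with Macrometastases", "Nodes with macrometastases: —",
    types = RESECT)
num(S, "Number of Nodes with Micrometastases", "ln_micro",
    "Number of Nodes with Micrometastases", "Nodes with micrometastases: —",
    types = RESECT)
num(S, "Number of Nodes with Isolated Tumor Cells", "ln_itc",
    "Number of Nodes with Isolated Tumor Cells", "Nodes with ITCs: —",
    types = RESECT)
num(S, "Size of Largest Metastatic Deposit", "ln_largest_deposit",
    "Size of Largest Metastatic Deposit", "Largest deposit: — mm",
    types = RESECT)
add(S, "Extranodal Extension", "extranodal_extension", "Extranodal Extension",
    "categorical", YN3, types = RESECT)
add(S, "Sentinel Node Status", "sentinel_node_status", "Sentinel Node Status",
    "categorical", opt("Negative", "Positive", "Not evaluated"), types = RESECT)
add(S, "Axillary Dissection", "axillary_dissection",
    "Axillary Dissection Performed", "categorical", opt("Yes", "No"),
    types = RESECT)
add(S, "Intramammary Nodes", "intramammary_nodes", "Intramammary Nodes",
    "categorical", YN, types = RESECT)
add(S, "Method of Node Evaluation", "node_eval_method",
    "Method of Node Evaluation", "categorical",
    opt("H&E only", "H&E and immunohistochemistry", "Molecular assay"),
    types = RESECT)
add(S, "Node Status Overall", "node_status_overall", "Node Status Overall",
    "categorical", opt("All nodes negative", "Node(s) positive",
                       "No nodes examined"), types = RESECT)
add(S, "Treatment Effect in Nodes", "treatment_effect_nodes",
    "Treatment Effect in Nodes", "categorical",
    opt("No known presurgical therapy", "No definite response",
        "Probable or definite response"), types = RESECT)
add(S, "Node Sampling Comment", "node_sampling_comment",
    "Node Sampling Comment", "free_text", types = RESECT)

## -------- section 5: distant metastasis (5 subsections) --------
S <- "distant metastasis"
add(S, "Distant Metastasis Status", "distant_met_status",
    "Distant Metastasis Status", "categorical",
    opt("Not applicable", "Cannot be assessed", "Distant metastasis present"))
add(S, "Distant Site(s) Involved", "distant_sites", "Distant Site(s) Involved",
    "categorical", opt("Bone", "Liver", "Lung", "Brain",
                       "Nonregional lymph node", "Other site (specify)"))
add(S, "Method of Confirmation", "distant_met_method",
    "Method of Metastasis Confirmation", "categorical",
    opt("Histologic confirmation", "Cytologic confirmation",
        "Imaging only", "Clinical assessment only"))
add(S, "Nonregional Lymph Nodes", "nonregional_nodes",
    "Nonregional Lymph Nodes", "categorical",
    opt("Not sampled", "Negative for tumor", "Positive for tumor"))
add(S, "Metastasis Comment", "metastasis_comment", "Metastasis Comment",
    "free_text")

## -------- section 6: pTNM classification (13 subsections) --------
S <- "pTNM classification"
add(S, "TNM Descriptors", "tnm_descriptors", "TNM Descriptors", "categorical",
    opt("Not applicable", "m (multiple)", "r (recurrent)", "y (posttreatment)"))
add(S, "pT Category", "pt_category", "Primary Tumor (pT)", "categorical",
    opt("pTX", "pT0", "pTis (DCIS)", "pT1mi", "pT1a", "pT1b", "pT1c",
        "pT2", "pT3", "pT4a", "pT4b", "pT4c", "pT4d"))
add(S, "pN Category", "pn_category", "Regional Lymph Nodes (pN)",
    "categorical",
    opt("pNX", "pN0", "pN0(i+)", "pN0(mol+)", "pN1mi", "pN1a", "pN1b", "pN1c",
        "pN2a", "pN2b", "pN3a", "pN3b", "pN3c"), types = RESECT)
add(S, "pM Category", "pm_category", "Distant Metastasis (pM)", "categorical",
    opt("Not applicable", "pM1"))
add(S, "Residual Tumor Classification", "residual_tumor",
    "Residual Tumor (R)", "categorical",
    opt("R0 (no residual tumor)", "R1 (microscopic residual tumor)",
        "R2 (macroscopic residual tumor)", "RX (cannot be assessed)"),
    types = RESECT)
add(S, "Stage Group", "stage_group", "Anatomic Stage Group", "categorical",
    opt("Stage 0", "Stage IA", "Stage IB", "Stage IIA", "Stage IIB",
        "Stage IIIA", "Stage IIIB", "Stage IIIC", "Stage IV"))
num(S, "pT Size Dimension", "pt_size_dimension", "pT Size Dimension",
    "Size for pT: — mm")
num(S, "pN Positive Node Count", "pn_positive_count",
    "Number of Positive Nodes for pN", "Positive nodes: —", types = RESECT)
add(S, "Classification Basis", "classification_basis", "Classification Basis",
    "categorical", opt("Pathologic (pTNM)", "Posttreatment pathologic (ypTNM)"))
add(S, "Multiple Primary Tumors", "multiple_primaries",
    "Multiple Primary Tumors", "categorical", YN)
add(S, "Post-treatment Classification", "posttreatment_class",
    "Post-treatment Classification Applied", "categorical", opt("Yes", "No"))
add(S, "TNM Edition", "tnm_edition", "AJCC TNM Edition", "categorical",
    opt("8th edition", "9th edition"))
add(S, "Staging Comment", "staging_comment", "Staging Comment", "free_text")

## -------- section 7: additional findings (8 subsections) --------
S <- "additional findings"
add(S, "Epithelial Findings", "adh", "Additional Findings", "categorical",
    opt("Atypical ductal hyperplasia", "Atypical lobular hyperplasia",
        "Usual ductal hyperplasia", "Flat epithelial atypia",
        "Columnar cell change", "None identified"),
    synonyms = "ADH=>Atypical ductal hyperplasia|ALH=>Atypical lobular hyperplasia")
add(S, "Microcalcification Findings", "calc_findings",
    "Microcalcification Findings", "categorical",
    opt("Not identified", "Present in benign tissue", "Present in carcinoma"))
add(S, "Biopsy Site Changes", "biopsy_site_changes", "Biopsy Site Changes",
    "categorical", YN)
add(S, "Benign Lesions", "benign_lesions", "Benign Lesions", "categorical",
    opt("Fibroadenoma", "Intraductal papilloma", "Radial scar",
        "Sclerosing adenosis", "Fat necrosis", "None identified"))
add(S, "Inflammatory Findings", "inflammatory_findings",
    "Inflammatory Findings", "categorical",
    opt("Not identified", "Chronic inflammation", "Abscess", "Granulomas"))
add(S, "Prior Treatment Changes", "prior_treatment_changes",
    "Prior Treatment Changes", "categorical", YN)
add(S, "Incidental Findings", "incidental_findings", "Incidental Findings",
    "free_text")
add(S, "Additional Findings Comment", "additional_findings_comment",
    "Additional Findings Comment", "free_text")

## -------- section 8: comments (2 subsections) --------
S <- "comments"
add(S, "Report Comment", "comments", "Comment(s)", "free_text")
add(S, "Clinical History", "clinical_history", "Clinical History", "free_text")

core <- do.call(rbind, rows)
stopifnot(!anyDuplicated(core$field_id), !anyDuplicated(core$label))

n_sections    <- length(unique(core$section))
n_subsections <- nrow(unique(core[, c("section", "subsection")]))
cat("core:", n_sections, "sections,", n_subsections, "subsections,",
    nrow(core), "fields\n")
stopifnot(n_sections == 8L, n_subsections == 86L)

## Companion fields: CAP checklists pair most categorical elements with an
## "other, specify" free-text element and often a per-element comment.
## Append companions deterministically, in schema order, until 229 fields.
target <- 229L
need <- target - nrow(core)
cat_rows <- which(core$value_kind == "categorical")
companions <- list()
mk <- function(parent, suffix, label_suffix) {
  data.frame(section = parent$section, subsection = parent$subsection,
             field_id = paste0(parent$field_id, suffix),
             label = paste0(parent$label, label_suffix),
             value_kind = "free_text", options = "", numeric_template = "",
             synonyms = "", report_types = parent$report_types,
             stringsAsFactors = FALSE)
}
for (i in cat_rows) {
  if (length(companions) >= need) break
  companions[[length(companions) + 1L]] <- mk(core[i, ], "_other", ", Other (specify)")
}
for (i in cat_rows) {
  if (length(companions) >= need) break
  companions[[length(companions) + 1L]] <- mk(core[i, ], "_comment", " Comment")
}
stopifnot(length(companions) == need)
schema <- rbind(core, do.call(rbind, companions))
# keep hierarchy order: sections in first-seen order, fields grouped by subsection
sec_order <- unique(core$section)
sub_key <- paste(core$section, core$subsection, sep = "\r")
sub_order <- unique(sub_key)
key <- paste(schema$section, schema$subsection, sep = "\r")
schema <- schema[order(match(key, sub_order)), ]
rownames(schema) <- NULL

stopifnot(nrow(schema) == 229L,
          !anyDuplicated(schema$field_id), !anyDuplicated(schema$label),
          nrow(unique(schema[, c("section", "subsection")])) == 86L,
          length(unique(schema$section)) == 8L)

out <- "inst/extdata/schema/breast_synoptic_schema.csv"
con <- file(out, open = "w", encoding = "UTF-8")
write.csv(schema, con, row.names = FALSE)
close(con)
cat("wrote", out, ":", nrow(schema), "fields\n")
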