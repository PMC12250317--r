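# Machine-readable registry of every equation: output variable, required
# cohort columns, per-equation sex/race coding, and whether the equation is
# part of the default tested comparison families (the two amputee-specific
# Cavedon skinfold models are registered but excluded by default because
# they need the axillary/chest folds that restricted-profile protocols do
# not collect).

.spec <- function(id, label, output, needs, sex_coding = NA_character_,
                  race_coding = NA_character_, height_unit = NA_character_,
                  tested = TRUE, citation = NA_character_, notes = NA_character_) {
  data.frame(equation_id = id, label = label, output = output,
             required_inputs = paste(needs, collapse = ";"),
             sex_coding = sex_coding, race_coding = race_coding,
             height_unit = height_unit, tested = tested,
             citation = citation, notes = notes,
             stringsAsFactors = FALSE)
}

.registry_rows <- function() {
  sk <- function(...) paste0("sk_", c(...))
  rows <- list(
    # body density (building blocks for the 16 composite FP entries)
    .spec("durnin_womersley", "Durnin & Womersley", "BD", c("sex", sk("bi", "tr", "ss", "si")),
          sex_coding = "sex-specific formula", citation = "durnin1974"),
    .spec("forsyth_sinning", "Forsyth & Sinning", "BD", sk("ss", "ab"), citation = "forsyth1973"),
    .spec("katch_mcardle", "Katch & McArdle", "BD", sk("tr", "ss", "ab"), citation = "katch1973"),
    .spec("nagamine_suzuki", "Nagamine & Suzuki", "BD", sk("tr", "ss"), citation = "nagamine1964"),
    .spec("sloan", "Sloan", "BD", sk("th", "ss"), citation = "sloan1967"),
    .spec("wilmore_behnke", "Wilmore & Behnke", "BD", sk("ab", "th"), citation = "wilmore1969"),
    .spec("withers", "Withers", "BD", sk("tr", "ss", "bi", "si", "ab", "th", "c"),
          citation = "withers1987"),
    .spec("white", "White", "BD", sk("si", "th"), citation = "white1980"),
    # direct fat percentage
    .spec("eston", "Eston", "FP", sk("bi", "tr", "ss", "si", "th", "c"), citation = "eston2005"),
    .spec("evans", "Evans", "FP", c("sex", "race", sk("ab", "th", "tr")),
          sex_coding = "male=1;female=0", race_coding = "afro_descendant=1;other=0",
          citation = "evans2005"),
    .spec("oconnor", "O'Connor", "FP", sk("tr", "si", "th"), citation = "oconnor2010",
          notes = "printed second term is linear; quadratic variant via options"),
    .spec("carter", "Carter", "FP", c("sex", sk("tr", "bi", "si", "ss", "th", "c")),
          sex_coding = "sex-specific formula", citation = "carter1982"),
    .spec("faulkner", "Faulkner", "FP", c("sex", sk("tr", "ss", "si", "ab")),
          sex_coding = "sex-specific formula", citation = "faulkner1968"),
    .spec("slaughter", "Slaughter", "FP", c("sex", sk("tr", "ss")),
          sex_coding = "sex-specific formula", citation = "slaughter1988"),
    .spec("yuhasz", "Yuhasz", "FP", c("sex", sk("tr", "ss", "si", "ab", "th", "c")),
          sex_coding = "sex-specific formula", citation = "yuhasz1974"),
    .spec("minematsu", "Minematsu", "FP", c("sex", "age", "body_weight_kg", "height_cm", "circ_waist"),
          sex_coding = "male=1;female=2", citation = "minematsu2011"),
    .spec("hastuti", "Hastuti", "FP", c("sex", sk("tr", "si")),
          sex_coding = "male=1;female=0", citation = "hastuti2018"),
    .spec("deurenberg", "Deurenberg", "FP", c("sex", "age", "body_weight_kg", "height_cm"),
          sex_coding = "male=1;female=0", citation = "deurenberg1991"),
    .spec("lean_wc", "Lean (waist circumference)", "FP", c("sex", "age", "circ_waist"),
          sex_coding = "sex-specific formula", citation = "lean1996"),
    .spec("lean_bmi", "Lean (BMI)", "FP", c("sex", "age", "body_weight_kg", "height_cm"),
          sex_coding = "sex-specific formula", citation = "lean1996"),
    .spec("lean_bmi_tr", "Lean (BMI + triceps)", "FP",
          c("sex", "age", "body_weight_kg", "height_cm", sk("tr")),
          sex_coding = "sex-specific formula", citation = "lean1996"),
    .spec("lean_log4sk", "Lean (log10 sum of 4 skinfolds)", "FP",
          c("sex", "age", sk("bi", "tr", "ss", "si")),
          sex_coding = "sex-specific formula", citation = "lean1996"),
    .spec("gomez_ambrosi", "Gomez-Ambrosi", "FP", c("sex", "age", "body_weight_kg", "height_cm"),
          sex_coding = "male=0;female=1", citation = "gomezambrosi2012"),
    .spec("isak5_fp", "ISAK 5-component (Kerr) fat %", "FP",
          c("body_weight_kg", "height_cm", sk("tr", "ss", "si", "ab", "th", "c")),
          height_unit = "cm", citation = "kerr1988",
          notes = "adipose mass via Z-score standardisation; literal printed form via options"),
    .spec("lee_dh_fp", "Lee DH fat %", "FP",
          c("sex", "age", "race", "body_weight_kg", "height_cm",
            "circ_waist", "circ_arm", "circ_calf", "circ_thigh", sk("tr", "ss")),
          sex_coding = "sex-specific formula",
          race_coding = "mexican;hispanic;afro_descendant;other offsets", citation = "lee2017"),
    .spec("giro", "Giro", "FP", c("circ_waist", sk("tr", "si", "ab", "th")),
          citation = "giro2023"),
    .spec("cavedon1", "Cavedon 1 (amputee-specific)", "FP", sk("th", "ab", "ss", "ax"),
          tested = FALSE, citation = "cavedon2023"),
    .spec("cavedon2", "Cavedon 2 (amputee-specific)", "FP",
          sk("bi", "tr", "ss", "ax", "ch", "si", "ab", "th", "c"),
          tested = FALSE, citation = "cavedon2023"),
    # fat mass
    .spec("al_guindan", "Al-Guindan", "FM",
          c("sex", "age", "body_weight_kg", "height_cm", "circ_waist"),
          sex_coding = "sex-specific formula", citation = "alguindan2020"),
    .spec("de_rose_fm", "De Rose & Guimaraes FM", "FM",
          c("body_weight_kg", sk("ss", "tr", "ssp", "ab")), citation = "derose1980"),
    .spec("isak5_fm", "ISAK 5-component (Kerr) FM", "FM",
          c("height_cm", sk("tr", "ss", "si", "ab", "th", "c")),
          height_unit = "cm", citation = "kerr1988"),
    .spec("heitmann", "Heitmann", "FM", c("sex", "age", "body_weight_kg", "height_cm"),
          sex_coding = "sex-specific weight coefficient", citation = "heitmann1990"),
    .spec("lee_dh_fm", "Lee DH FM", "FM",
          c("sex", "age", "race", "body_weight_kg", "height_cm",
            "circ_waist", "circ_arm", "circ_calf", "circ_thigh", sk("tr", "ss")),
          sex_coding = "sex-specific formula",
          race_coding = "mexican;hispanic;afro_descendant;other offsets", citation = "lee2017"),
    .spec("salamat_fm", "Salamat FM", "FM", c("sex", "body_weight_kg", "height_cm"),
          sex_coding = "male=1;female=0", citation = "salamat2015"),
    # lean percentage
    .spec("lee_rc_lp", "Lee RC lean %", "LP",
          c("sex", "age", "race", "body_weight_kg", "height_cm",
            "circ_arm", "circ_thigh", "circ_calf", sk("tr", "th", "c")),
          sex_coding = "male=1;female=0",
          race_coding = "asian=-2;afro_descendant=1.1;other=0",
          height_unit = "m", citation = "lee2000"),
    .spec("poortmans", "Poortmans", "LP",
          c("sex", "age", "body_weight_kg", "height_cm",
            "circ_arm", "circ_thigh", "circ_calf", sk("tr", "th", "c")),
          sex_coding = "male=1;female=0", height_unit = "m", citation = "poortmans2005"),
    .spec("isak5_lp", "ISAK 5-component (Kerr) lean %", "LP",
          c("body_weight_kg", "height_cm", "circ_arm", "circ_forearm", "circ_thigh",
            "circ_calf", "circ_chest", sk("tr", "th", "c", "ss")),
          height_unit = "cm", citation = "kerr1988"),
    # lean mass
    .spec("de_rose_lm", "De Rose & Guimaraes LM", "LM",
          c("body_weight_kg", "height_cm", "diam_wrist", "diam_femur",
            sk("ss", "tr", "ssp", "ab")),
          citation = "derose1980", notes = "closure: FM + bone + residual + LM = BW"),
    .spec("heymsfield", "Heymsfield", "LM", c("sex", "height_cm", "circ_arm", sk("tr")),
          sex_coding = "sex-specific area constant", citation = "heymsfield1982",
          notes = "height coefficient 0.284 as printed; 0.0264 via options"),
    .spec("lee_rc_1", "Lee RC 1", "LM",
          c("sex", "age", "race", "height_cm", "circ_arm", "circ_thigh", "circ_calf",
            sk("tr", "th", "c")),
          sex_coding = "male=1;female=0",
          race_coding = "asian=-2;afro_descendant=1.1;other=0",
          height_unit = "m", citation = "lee2000"),
    .spec("lee_rc_2", "Lee RC 2", "LM", c("sex", "age", "race", "body_weight_kg", "height_cm"),
          sex_coding = "male=1;female=0",
          race_coding = "asian=-1.2;afro_descendant=1.4;other=0",
          height_unit = "m", citation = "lee2000"),
    .spec("doupe", "Doupe", "LM",
          c("height_cm", "circ_arm", "circ_thigh", "circ_calf", sk("tr", "th", "c")),
          height_unit = "m", citation = "doupe1997"),
    .spec("isak5_lm", "ISAK 5-component (Kerr) LM", "LM",
          c("height_cm", "circ_arm", "circ_forearm", "circ_thigh", "circ_calf",
            "circ_chest", sk("tr", "th", "c", "ss")),
          height_unit = "cm", citation = "kerr1988"),
    .spec("janmahasatian", "Janmahasatian", "LM", c("sex", "body_weight_kg", "height_cm"),
          sex_coding = "sex-specific formula", citation = "janmahasatian2005"),
    .spec("olshvang", "Olshvang", "LM",
          c("sex", "age", "race", "body_weight_kg", "height_cm", "circ_waist"),
          sex_coding = "sex-specific formula",
          race_coding = "hispanic;afro_descendant;other offsets", citation = "olshvang2021"),
    .spec("chien", "Chien", "LM",
          c("sex", "body_weight_kg", "height_cm", "circ_forearm", "circ_hip"),
          sex_coding = "male=1;female=0", citation = "chien2008"),
    .spec("lee_dh_lm", "Lee DH LM", "LM",
          c("sex", "age", "race", "body_weight_kg", "height_cm",
            "circ_waist", "circ_arm", "circ_calf", "circ_thigh", sk("tr", "ss")),
          sex_coding = "sex-specific formula",
          race_coding = "mexican;hispanic;afro_descendant;other offsets", citation = "lee2017"),
    .spec("kulkarni3", "Kulkarni equation 3", "LM",
          c("sex", "age", "body_weight_kg", "height_cm", sk("bi", "tr", "ss", "si")),
          sex_coding = "sex-specific formula", citation = "kulkarni2013"),
    .spec("kulkarni4", "Kulkarni equation 4", "LM",
          c("sex", "age", "body_weight_kg", "height_cm", "circ_arm", "circ_calf",
            "circ_hip", sk("bi", "tr", "ss", "si")),
          sex_coding = "sex-specific formula", citation = "kulkarni2013"),
    .spec("salamat_lm", "Salamat LM", "LM",
          c("sex", "age", "body_weight_kg", "height_cm", "circ_waist"),
          sex_coding = "male=1;female=0", citation = "salamat2015")
  )
  do.call(rbind, rows)
}

#' Full equation registry
#'
#' One row per registered equation, including the eight body-density
#' equations, their sixteen composite `"<bd>+<converter>"` fat-percentage
#' entries, and the direct FP/FM/LP/LM equations. The `tested` flag marks
#' the default comparison families (FP 34, FM 6, LP 3, LM 13 entries).
#'
#' @return data.frame of equation specifications.
#' @export
equation_registry <- function() {
  base <- .registry_rows()
  bd <- base[base$output == "BD", ]
  comps <- do.call(rbind, lapply(seq_len(nrow(bd)), function(i) {
    do.call(rbind, lapply(c("siri", "brozek"), function(cv) {
      row <- bd[i, ]
      row$equation_id <- paste0(row$equation_id, "+", cv)
      row$label <- paste(row$label, "+", if (cv == "siri") "Siri" else "Brozek")
      row$output <- "FP"
      row$notes <- paste0("two-compartment conversion (", cv, ")")
      row
    }))
  }))
  out <- rbind(base, comps)
  rownames(out) <- NULL
  out
}

#' List equations, optionally filtered by output variable
#'
#' @param output optional filter, one of `"BD"`, `"FP"`, `"FM"`, `"LP"`,
#'   `"LM"`.
#' @param tested_only logical; keep only the default comparison families
#'   (drops the Cavedon amputee-specific entries, which need skinfold sites
#'   outside the restricted profile). Default `TRUE`.
#' @return data.frame of equation specifications in deterministic order.
#' @export
#' @examples
#' nrow(list_equations("FM"))  # 6
list_equations <- function(output = NULL, tested_only = TRUE) {
  reg <- equation_registry()
  if (tested_only) reg <- reg[reg$tested, ]
  if (!is.null(output)) {
    output <- match.arg(output, c("BD", "FP", "FM", "LP", "LM"))
    reg <- reg[reg$output == output, ]
  }
  reg <- reg[order(match(reg$output, c("BD", "FP", "FM", "LP", "LM")),
                   reg$equation_id), ]
  rownames(reg) <- NULL
  reg
}

#' Export the registry as JSON
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
registry_to_json <- function(path) {
  reg <- equation_registry()
  reg$required_inputs <- strsplit(reg$required_inputs, ";", fixed = TRUE)
  jsonlite::write_json(reg, path, pretty = TRUE, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
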