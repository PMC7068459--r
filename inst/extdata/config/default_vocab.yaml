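# Default class vocabulary and terminology acceptance lists.
#
# Everything here is editable configuration: the drug-class label set, the
# ATC class names and MED-RT mechanism-of-action names accepted as
# antihypertensive, the string(s) denoting hypertension in may_treat output,
# dose-form screening tokens, ingredient exclusion lists, and the RxNorm
# term-type policy for RxCUI-keyed maps.
#
# Combination class labels are written as component labels joined with "+"
# (e.g. THIAZIDE+ACE) and are implicitly part of the vocabulary whenever all
# components are.

labels:
  - ACE
  - ARB
  - BETA_BLOCKER
  - CCB
  - LOOP_DIURETIC
  - THIAZIDE
  - ALDOSTERONE_ANTAGONIST
  - DIRECT_RENIN_INHIBITOR
  - ALPHA1_BLOCKER
  - POTASSIUM_SPARING
  - VASODILATOR
  - CENTRAL_ACTING
  - OTHER

# ATC class names (matched case-insensitively against the batch export's
# class-name field) accepted as antihypertensive, with the drug-class
# label(s) they confer. Combination ATC classes confer multiple labels.
atc_class_names:
  "ace inhibitors, plain": [ACE]
  "ace inhibitors, combinations": [ACE]
  "ace inhibitors and diuretics": [ACE, THIAZIDE]
  "ace inhibitors and calcium channel blockers": [ACE, CCB]
  "angiotensin ii receptor blockers (arbs), plain": [ARB]
  "angiotensin ii receptor blockers (arbs) and diuretics": [ARB, THIAZIDE]
  "angiotensin ii receptor blockers (arbs) and calcium channel blockers": [ARB, CCB]
  "beta blocking agents": [BETA_BLOCKER]
  "beta blocking agents and thiazides": [BETA_BLOCKER, THIAZIDE]
  "beta blocking agents and other diuretics": [BETA_BLOCKER, LOOP_DIURETIC]
  "selective calcium channel blockers with mainly vascular effects": [CCB]
  "selective calcium channel blockers with direct cardiac effects": [CCB]
  "high-ceiling diuretics": [LOOP_DIURETIC]
  "low-ceiling diuretics, thiazides": [THIAZIDE]
  "low-ceiling diuretics, excl. thiazides": [THIAZIDE]
  "aldosterone antagonists": [ALDOSTERONE_ANTAGONIST]
  "potassium-sparing agents": [POTASSIUM_SPARING]
  "renin-inhibitors": [DIRECT_RENIN_INHIBITOR]
  "alpha-adrenoreceptor antagonists": [ALPHA1_BLOCKER]
  "antiadrenergic agents, centrally acting": [CENTRAL_ACTING]
  "antiadrenergic agents, peripherally acting": [ALPHA1_BLOCKER]
  "arteriolar smooth muscle, agents acting on": [VASODILATOR]
  "other antihypertensives": [OTHER]

# MED-RT has_MoA class names accepted as antihypertensive (matched
# case-insensitively), with the drug-class label(s) they confer.
medrt_moa_names:
  "angiotensin-converting enzyme inhibitors": [ACE]
  "angiotensin 2 receptor antagonists": [ARB]
  "adrenergic beta-antagonists": [BETA_BLOCKER]
  "adrenergic beta1-antagonists": [BETA_BLOCKER]
  "adrenergic beta2-antagonists": [BETA_BLOCKER]
  "calcium channel antagonists": [CCB]
  "loop diuretics": [LOOP_DIURETIC]
  "thiazide diuretics": [THIAZIDE]
  "thiazide-like diuretics": [THIAZIDE]
  "aldosterone antagonists": [ALDOSTERONE_ANTAGONIST]
  "renin inhibitors": [DIRECT_RENIN_INHIBITOR]
  "adrenergic alpha1-antagonists": [ALPHA1_BLOCKER]
  "potassium-sparing diuretics": [POTASSIUM_SPARING]
  "vasodilating agents": [VASODILATOR]
  "potassium channel interactions": [VASODILATOR]
  "adrenergic alpha2-agonists": [CENTRAL_ACTING]
  "norepinephrine depleting agents": [OTHER]

# Strings denoting hypertension in MED-RT may_treat output (case-insensitive
# exact match).
may_treat_hypertension:
  - "hypertension"

# Dose-form tokens that flag an entry as a non-systemic product.
dose_form_tokens:
  - "ophthalmic"
  - "topical"

# Alpha-blockers primarily indicated for benign prostatic hyperplasia.
bph_ingredients:
  - silodosin
  - alfuzosin
  - tamsulosin

# Ingredients excluded from curated maps during screening (BPH drugs,
# sacubitril combinations, and timolol under the name-map conservatism rule).
excluded_ingredients:
  - silodosin
  - alfuzosin
  - tamsulosin
  - sacubitril
  - timolol

# RxNorm term-type policy for RxCUI-keyed maps.
term_types_included: [SCD, SBD, SCDF]
term_types_excluded: [IN, MIN, PIN]

# Tokens that terminate ingredient scanning in a raw medication name
# (strength units and dose-form words); numerals and percent strings always
# terminate.
dose_tokens:
  - mg
  - ml
  - mcg
  - meq
  - hr
  - oral
  - tablet
  - tab
  - capsule
  - cap
  - solution
  - suspension
  - injection
  - injectable
  - chewable
  - extended
  - release
  - er
  - xl
  - xr
  - sr
  - hcl

# Ingredient synonyms/abbreviations used when expanding combination-name
# permutations (canonical token -> synonyms).
synonyms:
  hydrochlorothiazide: [hctz]
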