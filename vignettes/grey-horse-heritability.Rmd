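---
title: "Decomposing the inheritance of Grey-horse pigmentation traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the inheritance of Grey-horse pigmentation traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greyherit)
```

## The scientific problem

Grey horses are born coloured (black, bay, chestnut) and whiten
progressively because a dominant regulatory mutation at *STX17* drives
melanocyte loss. The same mutation is associated with a high incidence of
dermal melanoma, vitiligo-like depigmentation and coat speckling. None of
the four traits — melanoma grade (0–5), grey level (the colorimetric L\*
lightness, 0–100), vitiligo grade (0–3) and speckling grade (0–3) —
follows simple Mendelian inheritance: each mixes a large effect of the
*STX17* genotype (GG vs Gg among grey horses), a smaller effect of the
*ASIP* (agouti) locus for melanoma, a polygenic background, and strong
age dependence.

`greyherit` implements the quantitative-genetic machinery needed to
dissect such traits in a pedigreed population with repeated measurements:

1. a **repeated-records animal model** fitted by AI-REML,
   `y = Xb + Za + W pe + e`, with `Var(a) = A V_POLY` (A the pedigree
   relationship matrix), `Var(pe) = I V_pe` and `Var(e) = I V_e`; fixed
   effects are a stud-by-sex-by-year class, age in years, and the
   major-locus covariates (STX17 indicator GG = 0 / Gg = 1; ASIP additive
   code AA = 0 / Aa = 1 / aa = 2; ASIP dominance code AA = 0 / Aa = 1 /
   aa = 0);
2. a **variance decomposition** that converts a fitted locus regression
   coefficient into a locus variance via `V_locus = 2 p q alpha^2`
   (with `alpha = a + (p − q) d` in general, and `alpha = a` for the
   two-genotype Grey locus) and partitions phenotypic variance as
   `V_P = V_POLY + V_STX17 + V_ASIP + V_pe + V_e`, giving repeatability
   `R`, the permanent-environment share `c²`, and the heritability
   partition `h² = h²_POLY + h²_STX17 + h²_ASIP`;
3. a **three-scenario bivariate analysis** that diagnoses pleiotropy: the
   polygenic correlation is estimated (1) under a purely polygenic model
   on all horses, (2) with the major loci as fixed covariates, and
   (3) on GG homozygotes only. A correlation that collapses from
   scenario 1 to scenarios 2–3 was an artefact of the shared major gene;
   one that persists reflects genuinely shared polygenic background;
4. **Mendelian genotype deduction**: grey is dominant, so a coloured horse
   is `gg`, a grey parent of a coloured foal is `Gg`, a grey foal of a
   coloured parent is `Gg`, and further eliminations follow from
   Mendelian consistency through the pedigree.

## Worked example on simulated data

The package ships the four published trait parameterizations as generator
configurations, so every stage can be exercised without the (unreleased)
study data:

```{r, eval = FALSE}
cfg <- default_trait_configs()$melanoma
des <- study_design(n_founders = 60, n_generations = 3,
                    n_per_generation = 300, n_measured = 600,
                    mean_records = 3)
st <- simulate_study(cfg, des, seed = 1)
ph <- prepare_records(st$phenotypes, "melanoma")
fit <- fit_animal_model(ph, st$pedigree, traits = "melanoma",
                        genotypes = st$genotypes,
                        stx17 = TRUE, asip = TRUE)
decompose_fit(fit, st$genotypes)
```

## The REML engine

The restricted likelihood, its gradient and the average-information (AI)
matrix are all computed from one Cholesky factorisation of the
mixed-model-equation coefficient matrix per iteration, using the standard
identities `log|V| + log|X'V⁻¹X| = log|C| + log|G| + log|R|` and
`tr(P Z M Z') = tr(M (G⁻¹ − G⁻¹ C^{uu} G⁻¹))`. Updates are damped AI
steps — the proposal is projected onto the parameter space (variances at
their lower bounds, covariance matrices made positive semi-definite) and
step-halved until the restricted likelihood does not decrease — with an
expectation-maximisation step as fallback; EM steps never decrease the
likelihood, so the iteration is globally monotone. This matters in
practice: undamped AI steps routinely overshoot along the ridge where
`V_POLY` and `V_pe` trade off, and datasets whose optimum lies on the
`V_pe = 0` or `V_POLY = 0` boundary would otherwise crawl there at EM
speed.

Numerical choices, all overridable:

* convergence when `|Δ logL| < 1e-6` **and** the maximum relative
  parameter change is below `1e-5`; iteration cap 200 (an error carrying
  the full iteration trace);
* variance components bounded below at `1e-8` of the trait's phenotypic
  variance so the equations stay non-singular at boundary optima;
* correlations clamped to `|r| ≤ 0.999` during iteration;
* starting values `V_e = 0.5`, `V_POLY = 0.3`, `V_pe = 0.2` of the
  phenotypic variance (deterministic — the fit has no random element);
* standard errors from the inverse AI matrix at convergence; the SE of a
  genetic correlation by the delta method;
* fixed-effect identifiability by QR-based reduction of the class design
  to full column rank. Covariate estimates (age, locus effects) are
  invariant to this choice; a genuinely confounded covariate raises an
  error naming the term.

In bivariate models the residual covariance is fixed at zero: grey level
is recorded for young horses and the other traits for old ones, so two
traits' records are never paired observations of the same visit. The
polygenic and (optionally) permanent-environment covariances are
estimated. The restricted likelihood includes its normalising constant,
so it is directly comparable with a textbook dense evaluation of the REML
criterion; the test suite holds the two equal to `1e-6` on small
fixtures.

## The synthetic-data generator

The generator emulates the structure of the motivating study — a closed
multi-stud population of about 5,000 pedigree members over six
generations, with roughly 1,100 grey horses measured repeatedly across
nine years and six studs, sires averaging about 6 offspring and dams
about 2.3 — at any scale. Defaults mirror the study scale; tests use
smaller designs (stated in each test) to keep runtimes reasonable.
Specifics worth knowing:

* founder genotypes are drawn from Hardy–Weinberg proportions (defaults
  `p_G = 0.87`, `p_A = 0.52`, mid-range of the reported 0.85–0.89 and
  0.51–0.53) and dropped through the pedigree one random allele per
  parent; colour is grey iff at least one G allele;
* breeding values follow recursive Mendelian sampling,
  `u = 0.5 (u_s + u_d) + m`, `Var(m) = 0.5 (1 − (F_s + F_d)/2) V_POLY`,
  so that jointly `Var(u) = A ⊗ G0`;
* each record adds a stud-by-sex-by-year class effect drawn once per
  class. The study does not report the magnitude of these effects, so the
  default class variance is 10% of the phenotypic variance, configurable
  per trait (`v_class`);
* ages are drawn uniformly inside the trait's recording window — 12–84
  months for grey level, 84–240 months for the other traits; 84 months
  (seven years) belongs to **both** windows, matching the inclusive
  wording of the recording protocol. Measurement age is sampled directly
  rather than derived from birth year and visit date, which is the level
  of detail the model actually consumes;
* phenotypes are continuous by default even for graded traits; the
  published analysis fits linear models to the grades, so rounding to the
  grading scale is offered only as a robustness stressor
  (`round_to_scale = TRUE`). A consequence: unbounded Gaussian records
  can fall outside the nominal grading scale, so the scale check of
  `prepare_records()` — meant for validating real graded data — would
  truncate the tails of raw synthetic data and bias variance components.
  Simulated studies are therefore analysed as generated;
* grey level is generated as one pre-averaged record per visit (the
  four-site averaging of the colorimeter protocol happens upstream of the
  model);
* one shared set of measured animals serves all traits of a simulated
  study, whereas the study's per-trait data sets overlapped only partly —
  irrelevant for the univariate and scenario analyses, but worth knowing
  when comparing record counts.

What passing tests on these simulations do **not** show: robustness to
the ordinal measurement process (grades are generated Gaussian),
selective genotyping or non-random missingness, age-trajectory
non-linearity, and pedigree errors. Those are properties of real data the
generator deliberately does not emulate.

## Genotype deduction

Deduction is constraint propagation over parent–offspring trios with
candidate-set semantics, run to a fixed point, plus an
assume-and-propagate refinement: every remaining candidate genotype is
tentatively asserted and eliminated if propagation then reaches a
Mendelian contradiction anywhere in the pedigree. The refinement captures
eliminations that flow through a mate or around pedigree loops, which
trio-local rules alone can miss; in the test suite the result matches an
exhaustive enumeration oracle (all genotype assignments consistent with
colour, measurements and Mendelian inheritance) on hundreds of random
small pedigrees. The procedure is monotone — candidate sets only shrink,
so re-running changes nothing — and conservative: a genotype is called
only when a single candidate remains, it never overwrites a measured
genotype, and a contradiction raises an error naming the trio. At ASIP,
where coat colour is uninformative, only the generic Mendelian
elimination applies. Analyses accept measured-plus-deduced genotypes by
default (the published analysis did the same after checking both ways);
scenario 3 offers `strict_gg = TRUE` to restrict to measured genotypes.

## Reproducing the published partition columns

Feeding the published univariate estimates (variance components and locus
regression coefficients) through `decompose_heritability()` reproduces
the published partition table. The per-data-set allele frequencies are
published only as ranges; `p_G = 0.85, p_A = 0.51` reproduces the
melanoma and speckling columns, while the grey-level column (R = 0.81,
h²_STX17 = 0.22, h² = 0.79 at the published V_P = 175.45) is matched at
`p_G = 0.885`, the mid-range value — a reminder that two-decimal table
entries pin the unprinted frequencies rather tightly. The published
abstract rounds vitiligo h² to 0.63 where the table prints 0.64; the
table is treated as canonical here.

## Design choices that were genuinely open

* **Unknown parents are founders** with zero relationship to earlier
  animals (no genetic groups): the study pedigree is described as
  complete, and at this population size group effects would be
  unidentifiable anyway.
* **Dense A, sparse A⁻¹**: the relationship matrix is built dense by the
  tabular method (a studbook of a few thousand fits comfortably), but the
  inverse used by the mixed-model equations is always assembled sparsely
  by Henderson's rules with inbreeding, and inbreeding itself comes from
  an independent L-row trace method — giving the tests a cross-method
  identity (`diag(A) = 1 + F`) for free.
* **Bivariate permanent-environment covariance** is estimated by default
  (animals measured for both traits identify it) but can be fixed at
  zero (`pe_cov = FALSE`).
* **Scenario-2 covariates**: STX17 for every trait, ASIP only for traits
  listed in `asip_traits` (default melanoma), mirroring the published
  model selection in which ASIP was non-significant elsewhere.
* The published analysis was run in a commercial REML package; the
  algorithmic choices above (AI with damped projected steps, EM
  fallback, MME-based likelihood identities) are this package's own and
  are validated against dense-matrix oracles rather than against that
  software.

## Known limitations

Bivariate (not higher-dimensional) multivariate models; no dominance or
epistatic polygenic variance (the study itself found the data
insufficient for those); no probabilistic genotype peeling — deduction is
exact-logic only; no genomic relationship matrices; dense-A construction
is intended for pedigrees up to a few thousand animals.
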