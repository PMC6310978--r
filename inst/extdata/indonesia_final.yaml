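schema_version: 1
name: indonesia-opp-tender
version: '1'
notes: 6 + 1 criteria elicited in the pilot workshop
price_weight: 0.4
price_cutoff_excess: 1.0
criteria:
- id: equivalence
  name: Equivalence with the reference (original) product
  definition: Evidence on health outcomes from pharmaceutical-, bioequivalence- and
    clinical trials
  is_price: no
  weight: 0.125264750378215
  categories:
  - label: no-pe-data
    level: 0
    score_fraction: 0.0
    description: No data on pharmaceutical equivalence
    is_exclusion: no
  - label: pe
    level: 1
    score_fraction: 0.166666666666667
    description: Pharmaceutical equivalence
    is_exclusion: no
  - label: interchangeability-local
    level: 2
    score_fraction: 0.333333333333333
    description: Interchangeability defined based on local criteria
    is_exclusion: no
  - label: be-local
    level: 3
    score_fraction: 0.5
    description: Bioequivalence proven based on local criteria
    is_exclusion: no
  - label: be-ema-fda
    level: 4
    score_fraction: 0.666666666666667
    description: Bioequivalence proven based on European EMA or US FDA criteria
    is_exclusion: no
  - label: therapeutic-equivalence
    level: 5
    score_fraction: 0.833333333333333
    description: Therapeutic equivalence proven in clinical trial
    is_exclusion: no
  - label: improved-efficacy-safety
    level: 6
    score_fraction: 1.0
    description: Improvement in efficacy and/or safety based on clinical trial data
    is_exclusion: no
- id: real-world-outcomes
  name: Real world clinical or economic outcomes
  definition: Evidence on effectiveness and costs (adherence, tolerability, non-drug
    costs) from real-world data
  is_price: no
  weight: 0.041754916792738
  categories:
  - label: no-rwd
    level: 0
    score_fraction: 0.0
    description: No real world data on equal tolerability, adherence or non-drug cost
    is_exclusion: no
  - label: intl-rwd-equal
    level: 1
    score_fraction: 0.25
    description: International real world data on equal outcomes
    is_exclusion: no
  - label: local-rwd-equal
    level: 2
    score_fraction: 0.5
    description: Local real world data on equal outcomes
    is_exclusion: no
  - label: intl-rwd-improved
    level: 3
    score_fraction: 0.75
    description: International real world data on improved outcomes
    is_exclusion: no
  - label: local-rwd-improved
    level: 4
    score_fraction: 1.0
    description: Local real world data on improved outcomes
    is_exclusion: no
- id: stability-formulation
  name: Product stability and drug formulation
  definition: Evidence on stability and drug formulation
  is_price: no
  weight: 0.125264750378215
  categories:
  - label: no-stability-data
    level: 0
    score_fraction: 0.0
    description: No data on product expiry or stability
    is_exclusion: no
  - label: non-inferior-local
    level: 1
    score_fraction: 0.25
    description: Data on non-inferior product expiry or stability in local environment
    is_exclusion: no
  - label: improved-expiry
    level: 2
    score_fraction: 0.5
    description: Data on improved product expiry
    is_exclusion: no
  - label: improved-stability-local
    level: 3
    score_fraction: 0.75
    description: Data on improved product stability in local environment
    is_exclusion: no
  - label: improved-expiry-and-stability
    level: 4
    score_fraction: 1.0
    description: Data on improved product expiry and stability in local environment
    is_exclusion: no
- id: quality-assurance
  name: Quality assurance
  definition: Evidence on manufacturing- and product quality and standardisation
  is_price: no
  weight: 0.187897125567322
  categories:
  - label: limited-info
    level: 0
    score_fraction: 0.0
    description: Limited information on quality assurance
    is_exclusion: no
  - label: non-gmp-api
    level: 1
    score_fraction: 0.25
    description: Local/non GMP quality assurance only for active product ingredient
    is_exclusion: no
  - label: non-gmp-full
    level: 2
    score_fraction: 0.5
    description: Local/non GMP quality assurance for the entire manufacturing process
    is_exclusion: no
  - label: who-gmp
    level: 3
    score_fraction: 0.75
    description: WHO GMP certification
    is_exclusion: no
  - label: eu-pics-gmp
    level: 4
    score_fraction: 1.0
    description: EU or PIC/S GMP
    is_exclusion: no
- id: supply-reliability
  name: Reliability of drug supply
  definition: Stability and reliability of drug supply (history and future guarantee)
  is_price: no
  weight: 0.083509833585477
  categories:
  - label: major-multiple-problems
    level: 0
    score_fraction: 0.0
    description: Major and multiple supply problems in the last 5 years
    is_exclusion: no
  - label: minor-frequent-problems
    level: 1
    score_fraction: 0.25
    description: Minor and fairly frequent supply problems in the last 5 years
    is_exclusion: no
  - label: single-problem
    level: 2
    score_fraction: 0.5
    description: Single precedence of supply problems in the last 5 years
    is_exclusion: no
  - label: no-problems
    level: 3
    score_fraction: 0.75
    description: No precedence of supply problems in the last 5 years
    is_exclusion: no
  - label: guaranteed-supply
    level: 4
    score_fraction: 1.0
    description: Manufacturer is financially capable and willing to guarantee supply
    is_exclusion: no
- id: pharmacovigilance
  name: Pharmacovigilance
  definition: Data collection and assessment on adverse events of pharmaceuticals
  is_price: no
  weight: 0.036308623298033
  categories:
  - label: no-pv-system
    level: 0
    score_fraction: 0.0
    description: No pharmacovigilance system
    is_exclusion: no
  - label: qualified-person
    level: 1
    score_fraction: 0.5
    description: Qualified person for pharmacovigilance
    is_exclusion: no
  - label: qualified-person-and-system
    level: 2
    score_fraction: 1.0
    description: Qualified person and sophisticated system to collect data
    is_exclusion: no
- id: price
  name: Price
  definition: Acquisition cost of the pharmaceutical product compared to the lowest
    price available
  is_price: yes
  weight: 0.4
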