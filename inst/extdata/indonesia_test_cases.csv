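product_id,price,equivalence,real-world-outcomes,stability-formulation,quality-assurance,macroeconomic-benefit,supply-reliability,pharmacovigilance,added-value-services
test-case-1,2200,interchangeability-local,no-rwd,non-inferior-local,non-gmp-api,moderate-local-investment,minor-frequent-problems,no-pv-system,no-service
test-case-2,2900,be-local,local-rwd-equal,improved-expiry,non-gmp-full,minor-local-investment,no-problems,qualified-person-and-system,major-service-demonstrated
test-case-3,3000,be-local,local-rwd-equal,improved-expiry,non-gmp-full,minor-local-investment,no-problems,qualified-person-and-system,major-service-demonstrated
test-case-4,3800,be-ema-fda,intl-rwd-equal,improved-stability-local,who-gmp,significant-local-investment,single-problem,qualified-person,service-available
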