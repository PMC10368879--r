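colitis	colitis|enterocolitis
pneumonitis	pneumonitis|lung inflammation
thyroid abnormalities	thyroid abnormalities|hypothyroidism|hyperthyroidism|thyroiditis
rash	rash|dermatitis|maculopapular rash
hepatitis	hepatitis|transaminitis|liver toxicity
myalgia	myalgia|muscle aches
arthralgia	arthralgia|joint pain
cardiotoxicity	cardiotoxicity|myocarditis|cardiomyopathy
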