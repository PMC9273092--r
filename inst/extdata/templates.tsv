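subcategory	template
married	anniversary mentioned pt currently {term} per intake anniversary
married	ceremony screening documented {term} noted on arrival ceremony filed
married	wedding banter pt reports {term} documented ring worn decades
married	mentioned discussion held pt confirmed {term} currently vows recalled fondly
married	wedding update noted {term} today celebrated recently
partnered	relationship described pt currently {term} per intake relationship
partnered	committed screening documented {term} noted on arrival committed filed
partnered	devoted steady pt reports {term} documented relationship longstanding devoted
partnered	described discussion held pt confirmed {term} currently committed decades together
partnered	devoted update noted {term} today described steady
relatives_unknown_involvement	estranged relations pt currently {term} per intake estranged
relatives_unknown_involvement	distant screening documented {term} noted on arrival distant filed
relatives_unknown_involvement	involvement unclear pt reports {term} documented estranged relations distant
relatives_unknown_involvement	relations discussion held pt confirmed {term} currently involvement degree unclear
relatives_unknown_involvement	involvement update noted {term} today estrangement suspected
caregiver_support	bathing assistance pt currently {term} per intake errands
caregiver_support	errands screening documented {term} noted on arrival errands filed
caregiver_support	chores helper pt reports {term} documented assistance bathing dressing
caregiver_support	assistance discussion held pt confirmed {term} currently errands chores covered
caregiver_support	chores update noted {term} today assistance arranged
living_with_others	household composition pt currently {term} per intake duplex
living_with_others	duplex screening documented {term} noted on arrival duplex filed
living_with_others	upstairs bedrooms pt reports {term} documented household duplex upstairs
living_with_others	composition discussion held pt confirmed {term} currently downstairs bedrooms shared
living_with_others	upstairs update noted {term} today household described
community_connection	bingo outings pt currently {term} per intake potluck
community_connection	potluck screening documented {term} noted on arrival potluck filed
community_connection	seniors center pt reports {term} documented bingo potluck outings
community_connection	outings discussion held pt confirmed {term} currently seniors center rides
community_connection	seniors update noted {term} today outings frequent
religious_connections	devotions observed pt currently {term} per intake scripture
religious_connections	scripture screening documented {term} noted on arrival scripture filed
religious_connections	hymnal bedside pt reports {term} documented devotions scripture hymnal
religious_connections	observed discussion held pt confirmed {term} currently sabbath observed weekly
religious_connections	hymnal update noted {term} today devotions continued
surrogate_identified	signature witnessed pt currently {term} per intake signature
surrogate_identified	notarized screening documented {term} noted on arrival notarized filed
surrogate_identified	forms signed pt reports {term} documented forms witnessed notarized
surrogate_identified	witnessed discussion held pt confirmed {term} currently signature filed properly
surrogate_identified	forms update noted {term} today notarized copy
unmarried	checkbox marked pt currently {term} per intake census
unmarried	census screening documented {term} noted on arrival census filed
unmarried	demographic fields pt reports {term} documented checkbox census marked
unmarried	marked discussion held pt confirmed {term} currently demographic fields complete
unmarried	demographic update noted {term} today checkbox ticked
living_alone	studio unit pt currently {term} per intake keys
living_alone	keys screening documented {term} noted on arrival keys filed
living_alone	locks entry pt reports {term} documented studio unit keys
living_alone	unit discussion held pt confirmed {term} currently locks changed recently
living_alone	locks update noted {term} today studio described
transitionally_situated	voucher requested pt currently {term} per intake motel
transitionally_situated	motel screening documented {term} noted on arrival motel filed
transitionally_situated	outreach worker pt reports {term} documented motel voucher requested
transitionally_situated	requested discussion held pt confirmed {term} currently outreach worker engaged
transitionally_situated	outreach update noted {term} today voucher pending
surrogate_unidentified	voicemail unanswered pt currently {term} per intake operator
surrogate_unidentified	operator screening documented {term} noted on arrival operator filed
surrogate_unidentified	directory searched pt reports {term} documented voicemail unanswered repeatedly
surrogate_unidentified	unanswered discussion held pt confirmed {term} currently directory searched twice
surrogate_unidentified	directory update noted {term} today voicemails left
palliative_care	dyspnea symptom pt currently {term} per intake titration
palliative_care	titration screening documented {term} noted on arrival titration filed
palliative_care	morphine comfort pt reports {term} documented symptom titration ongoing
palliative_care	symptom discussion held pt confirmed {term} currently dyspnea morphine titrated
palliative_care	morphine update noted {term} today symptom burden
hospice	enrollment benefit pt currently {term} per intake benefit
hospice	agency screening documented {term} noted on arrival agency filed
hospice	bereavement eligibility pt reports {term} documented agency enrollment benefit
hospice	benefit discussion held pt confirmed {term} currently bereavement services offered
hospice	bereavement update noted {term} today enrollment begun
advance_directives_available	binder scanned pt currently {term} per intake folder
advance_directives_available	folder screening documented {term} noted on arrival folder filed
advance_directives_available	copies legible pt reports {term} documented binder folder copies
advance_directives_available	scanned discussion held pt confirmed {term} currently scanned legible version
advance_directives_available	copies update noted {term} today binder received
advance_directives_unavailable	faxed awaiting pt currently {term} per intake awaiting
advance_directives_unavailable	requested screening documented {term} noted on arrival requested filed
advance_directives_unavailable	outside facility pt reports {term} documented faxed outside facility
advance_directives_unavailable	awaiting discussion held pt confirmed {term} currently awaiting faxed records
advance_directives_unavailable	outside update noted {term} today request faxed
lacking_capacity	pupils sluggish pt currently {term} per intake exam
lacking_capacity	commands screening documented {term} noted on arrival commands filed
lacking_capacity	orientation exam pt reports {term} documented orientation exam limited
lacking_capacity	sluggish discussion held pt confirmed {term} currently commands followed inconsistently
lacking_capacity	orientation update noted {term} today pupils checked
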