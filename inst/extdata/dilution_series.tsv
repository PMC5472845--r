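tastant	quality	molar_mass_g_mol	sample	conc_mM	start
sucrose	sweet	342.30	1	584.282793	0
sucrose	sweet	342.30	2	292.772422	0
sucrose	sweet	342.30	3	146.701724	0
sucrose	sweet	342.30	4	73.508618	1
sucrose	sweet	342.30	5	36.833187	0
sucrose	sweet	342.30	6	18.457493	0
sucrose	sweet	342.30	7	9.249197	0
sucrose	sweet	342.30	8	4.633363	0
sucrose	sweet	342.30	9	2.322524	0
sucrose	sweet	342.30	10	1.162723	0
sucrose	sweet	342.30	11	0.584283	0
sucrose	sweet	342.30	12	0.290885	0
sucrose	sweet	342.30	13	0.146392	0
sucrose	sweet	342.30	14	0.073357	0
citric acid	sour	192.12	1	46.845721	0
citric acid	sour	192.12	2	25.240735	0
citric acid	sour	192.12	3	13.599885	0
citric acid	sour	192.12	4	7.327712	1
citric acid	sour	192.12	5	3.948209	0
citric acid	sour	192.12	6	2.127316	0
citric acid	sour	192.12	7	1.146211	0
citric acid	sour	192.12	8	0.617583	0
citric acid	sour	192.12	9	0.332761	0
citric acid	sour	192.12	10	0.179315	0
citric acid	sour	192.12	11	0.096606	0
citric acid	sour	192.12	12	0.052051	0
citric acid	sour	192.12	13	0.028055	0
citric acid	sour	192.12	14	0.015095	0
sodium chloride	salty	58.44	1	342.231348	0
sodium chloride	salty	58.44	2	182.638604	0
sodium chloride	salty	58.44	3	97.468686	1
sodium chloride	salty	58.44	4	52.016085	0
sodium chloride	salty	58.44	5	27.759411	0
sodium chloride	salty	58.44	6	14.814339	0
sodium chloride	salty	58.44	7	7.906057	0
sodium chloride	salty	58.44	8	4.219199	0
sodium chloride	salty	58.44	9	2.251711	0
sodium chloride	salty	58.44	10	1.201574	0
sodium chloride	salty	58.44	11	0.641342	0
sodium chloride	salty	58.44	12	0.342231	0
quinine hydrochloride	bitter	396.91	1	3.130661	0
quinine hydrochloride	bitter	396.91	2	1.842925	0
quinine hydrochloride	bitter	396.91	3	1.084860	0
quinine hydrochloride	bitter	396.91	4	0.638619	0
quinine hydrochloride	bitter	396.91	5	0.375942	0
quinine hydrochloride	bitter	396.91	6	0.221294	0
quinine hydrochloride	bitter	396.91	7	0.130278	0
quinine hydrochloride	bitter	396.91	8	0.076685	1
quinine hydrochloride	bitter	396.91	9	0.045138	0
quinine hydrochloride	bitter	396.91	10	0.026567	0
quinine hydrochloride	bitter	396.91	11	0.015633	0
quinine hydrochloride	bitter	396.91	12	0.009196	0
quinine hydrochloride	bitter	396.91	13	0.005415	0
quinine hydrochloride	bitter	396.91	14	0.003193	0
quinine hydrochloride	bitter	396.91	15	0.001890	0
quinine hydrochloride	bitter	396.91	16	0.001098	0
quinine hydrochloride	bitter	396.91	17	0.000639	0
quinine hydrochloride	bitter	396.91	18	0.000383	0
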