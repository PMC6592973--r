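# Diplazium hachijoense complex: voucher, reproductive mode, ploidy,
# plastid trnL-F haplotype and nuclear AK1 allele constitution,
# transcribed from the published voucher table for the complex.
voucher	locality	species	mode	ploidy_2n_or_multiple	plastid	ak1
S. Serizawa 91648-1	Okinawa pref.: Kunigami village, Mt. Yonahadake	D. dilatatum	apo.		α1	A3A4
S. Serizawa 91648-2	Okinawa pref.: Nago city, Genka	D. dilatatum			α1	A1A4
K. Hatake 705	Kagoshima pref.: Amami city, Sumiyou village, Santaro-touge, 350m alt.	D. dilatatum	sex.	2x	α2	A1
K. Hatake 974	Kagoshima pref.: Amami city, Naze	D. dilatatum	sex.	2x	α1	A4
K. Hori 3082	Kagoshima pref.: Yakushima Is, Koseda, 70m alt.	D. dilatatum			α1	A6
K. Hori 3083	Kagoshima pref.: Yakushima Is, Koseda, 70m alt.	D. dilatatum			α1	A1A2
K. Hori 3125	Kagoshima pref.: Yakushima Is, Hara, 80m alt.	D. dilatatum			α1	A6
M. Takamiya 866	Mie pref.: Minamimuro county, Kiho-cho	D. takii	apo.	3x	β1	B2
K. Hori 2924	Fukuoka pref.: Kasuya county, Hisayama-machi, 140m alt.	D. takii			β1	B2
K. Hori 2958	Fukuoka pref.: Kasuya county, Hisayama-machi, 140m alt.	D. takii			β1	B2
K. Hori 2343	Mie pref.: Minamimuro county, Kiho-cho, 70m alt.	D. takii			β1	B2B3
K. Hori 3173	Kagoshima pref.: Yakushima Is, Isso-river, 390m alt.	D. doederleinii			γ2	C
K. Hatake 615	Kagoshima pref.: Amami city, Naze, Honchya-touge, 250m alt.	D. amamianum	sex.	2x	δ1	D1
K. Hatake 985	Kagoshima pref.: Amami city, Sumiyou village, Santaro-touge, 350m alt.	D. amamianum	sex.	2x	δ1	D1
K. Hatake 609	Kagoshima pref.: Amami city, Naze, Ooaza-asato	D. amamianum	sex.	2x	δ4	D1
K. Hori 3084	Kagoshima pref.: Yakushima Is, Koseda, 70m alt.	D. taiwanense			β2	A2B1
K. Hori 3080	Kagoshima pref.: Yakushima Is, Koseda, 71m alt.	D. taiwanense	apo.		α1	A1A6B1
K. Hori 3087	Kagoshima pref.: Yakushima Is, Isso-river, 200m alt.	D. okinawaense	apo.		δ2	A1B2
S. Serizawa 91663-1	Okinawa pref.: Nago city, Genka	D. sp. 1	apo.		α1	A1A5G
K. Hori 3158	Kagoshima pref.: Yakushima Is, Tabugawa, 200m alt.	D. conterminum			β1	B2F
K. Hori 2341	Mie pref.: Minamimuro county, Kiho-cho	D. virescens			β1	B2E
K. Hori 2342	Mie pref.: Minamimuro county, Kiho-cho	D. virescens			β1	B2E
K. Hori 3086	Kagoshima pref.: Yakushima Is, Miyanoura river, 20m alt.	D. virescens			β1	B1B2E
K. Hatake 773	Kagoshima pref.: Tokunoshima Is, Mt. Inokawadake, 200m alt.	D. hachijoense	apo.	3x	δ1	B2D1
K. Hatake 776	Kagoshima pref.: Tokunoshima Is, Mt. Inokawadake, 200m alt.	D. hachijoense	apo.	3x	δ2	B2D1
K. Hori 1681	Chiba pref.: Katori county, Tako-machi, Hayashi	D. hachijoense			δ3	B2D2
S. Serizawa 91664-1	Okinawa pref.: Nago city, Genka	D. hachijoense	apo.		δ1	B2D2
K. Hori 2957	Fukuoka pref.: Kasuya county, Hisayama-machi, 140m alt.	D. hachijoense			δ3	B2D2
M. Takamiya 528	Yamaguchi pref.: Nagato city, Ichinoo	D. hachijoense			δ3	B2D2
M. Takamiya 919	Mie pref.: Minamimuro county, Kiho-cho	D. hachijoense	apo.	3x	δ5	B2D3
K. Hatake 1010	Shizuoka pref.: Shimoda city, Renndaiji-onsenn, 100m alt.	D. hachijoense	apo.	3x	δ5	B2D3
K. Hatake 395	Kagoshima pref.: Tokunoshima Is, Mt. Inokawadake, 200m alt.	D. hachijoense	apo.	3x	δ1	B2D1
M. Takamiya 883	Mie pref.: Minamimuro county, Kiho-cho	D. hachijoense	apo.	3x	δ3	B2D2
M. Takamiya 893	Mie pref.: Minamimuro county, Kiho-cho	D. hachijoense	apo.	3x	δ3	B2D2
M. Takamiya 1883	Kagoshima pref.: Kagoshima city, Chuzann-cho, Takinoshita-river	D. sp. 3	apo.	3x	δ1	CD2
S. Serizawa 91654-1	Okinawa pref.: Kunigami village, Mt. Yonahadake	D. sp. 2			γ1	CK
S. Serizawa 91654-2	Okinawa pref.: Kunigami village, Mt. Yonahadake	D. sp. 2			γ1	CK
K. Hori 2338	Mie pref.: Minamimuro county, Kiho-cho	D. sp. 4			δ3	D1H1
M. Takamiya 929	Mie pref.: Minamimuro county, Kiho-cho	D. sp. 4	apo.	3x	δ1	D2H2
K. Hatake 1030	Kumamoto pref.: Amakusa city	D. sp. 4	apo.	3x	δ1	D2H2
K. Hori 2339	Mie pref.: Minamimuro county, Kiho-cho	D. nipponicum			ε	D2J
K. Hatake 1004	Kanagawa pref.: Minamiashigara city, Kano	D. nipponicum	sex.	4x	ε	D2J
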