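variable	level	prompt
age_bin	<=47	The patient is 47 years old or younger
age_bin	48-63	The patient is between 48 and 63 years old
age_bin	>=64	The patient is 64 years old or older
sex	male	The patient is male
sex	female	The patient is female
kps_bin	<=50	The Karnofsky performance status is 50 or lower
kps_bin	60-70	The Karnofsky performance status is between 60 and 70
kps_bin	>=80	The Karnofsky performance status is 80 or higher
who_grade	2	The tumor is WHO grade II
who_grade	3	The tumor is WHO grade III
who_grade	4	The tumor is WHO grade IV
histology	glioblastoma IDH-wt	The histopathology is glioblastoma, IDH wildtype
histology	astrocytoma IDH-mut	The histopathology is astrocytoma, IDH-mutant
histology	oligodendroglioma IDH-mut 1p/19q-codel	The histopathology is oligodendroglioma, IDH-mutant and 1p/19q-codeleted
idh	wildtype	The IDH gene is wildtype
idh	mutated	The IDH gene is mutated
codeletion_1p19q	non-codeleted	The 1p/19q chromosome arms are not codeleted
codeletion_1p19q	codeleted	The 1p/19q chromosome arms are codeleted
mgmtp	unmethylated	The MGMT promoter is unmethylated
mgmtp	methylated	The MGMT promoter is methylated
eor	gross total	The patient underwent gross total resection
eor	subtotal	The patient underwent subtotal resection
eor	biopsy	The patient underwent biopsy only
radiotherapy	received	The patient received radiation therapy
radiotherapy	not received	The patient did not receive radiation therapy
chemotherapy	received	The patient received chemotherapy
chemotherapy	not received	The patient did not receive chemotherapy
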