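motif_dq2.5.tsv	8eca35ffd2d28697f1812d5caf35bf28
motif_dq8.1.tsv	5accb8efd9dcec45fe18e4392fce52a0
qm_dq2.5_binder.tsv	0fa22960ec61f0b64090a5ea2a818c53
qm_dq2.5_nonbinder.tsv	20801f377527202e1e5119abaf4cd8a5
qm_dq8.1_binder.tsv	7de6446901f4693be4563c9cce824eea
qm_dq8.1_nonbinder.tsv	a8e5ea8410f32bc56fb48cf52417a7ed
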