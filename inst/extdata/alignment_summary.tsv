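sample	n_reads	read_length	n_unique_reads
NPB	77019774	50	55413403
9311	74384043	50	58116517
NPBx9311	81735674	50	68473811
9311xNPB	78026146	50	66122696
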